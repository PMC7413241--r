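# units=Gy_per_MBq_h
# nuclide=Lu-177
target,blood,heart,liver,lungs,spleen,kidneys,intestine,pancreas,stomach,bone,marrow,muscle,tumor,remainder
blood,0.0499766014986776,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0
heart,               0,0.56640148365168,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0
liver,               0,               0,0.0620147609837606,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0
lungs,               0,               0,               0,0.56640148365168,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0
spleen,               0,               0,               0,               0,0.84960222547752,               0,               0,               0,               0,               0,               0,               0,               0,               0
kidneys,               0,               0,               0,               0,               0,0.249883007493388,               0,               0,               0,               0,               0,               0,               0,               0
intestine,               0,               0,               0,               0,               0,               0,0.042480111273876,               0,               0,               0,               0,               0,               0,               0
pancreas,               0,               0,               0,               0,               0,               0,               0,0.28320074182584,               0,               0,               0,               0,               0,               0
stomach,               0,               0,               0,               0,               0,               0,               0,               0,0.339840890191008,               0,               0,               0,               0,               0
bone,               0,               0,               0,               0,               0,               0,               0,               0,               0,0.0339840890191008,               0,               0,               0,               0
marrow,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,0.339840890191008,               0,               0,               0
muscle,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,0.009440024727528,               0,               0
tumor,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,0.21240055636938,               0
remainder,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,               0,0.01309094338178
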