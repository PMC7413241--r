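# decay_corrected_to=injection
# nuclide=Y-86
organ,time_h,pct_ia_per_g,sd,n
blood,               4, 13.811961981946,2.02842309262768,3
blood,              24, 6.8582016718947,0.870544875191367,3
blood,              48,3.54830210229052,0.283354518262181,3
blood,              72, 1.1841502035051,0.21944730479189,3
bone,               4,0.833844932372477,0.183602536783729,3
bone,              24,2.05745297218225,0.380807202634395,3
bone,              48,1.82890381047983,0.164675367456791,3
bone,              72,1.59459412849008,0.190954092092089,3
heart,               4,5.20865610494399,0.461094870731547,3
heart,              24,2.88057816330911,0.177633911515533,3
heart,              48,1.36344124606393,0.316584207036225,3
heart,              72,0.70325174472122,0.0487477232241991,3
intestine,               4, 1.9534813063119,0.221660908154769,3
intestine,              24,4.17609040081637,0.0593137718986799,3
intestine,              48,3.74615980763191,0.330907289812808,3
intestine,              72, 2.1347485132535,0.0622943061906377,3
kidneys,               4,4.84116363001183,0.285725003494014,3
kidneys,              24,2.72414875560338,0.279665172681761,3
kidneys,              48,2.17763126261188,0.05980150827475,3
kidneys,              72,1.29298318469647,0.214600459443842,3
liver,               4,4.09022778566186,0.47548202847772,3
liver,              24,9.53286580126843,1.11599946963535,3
liver,              48,7.30307839619212,1.28075031681571,3
liver,              72,5.60928392187005,0.386534472990766,3
lungs,               4,3.11317172986867,0.332456621936755,3
lungs,              24,2.08300772885254,0.24753353526099,3
lungs,              48, 1.1119154532597,0.0887962410387675,3
lungs,              72,0.635984707811752,0.0118186309652674,3
muscle,               4,0.403970768463838,0.0410694414099454,3
muscle,              24,0.826413666997228,0.0779439405808044,3
muscle,              48,0.673288448837945,0.110682103884168,3
muscle,              72,0.597736214185209,0.12320159375189,3
spleen,               4,1.39549809468516,0.0836356986999768,3
spleen,              24,2.98686468917328,0.0319844565965229,3
spleen,              48,2.45462796560414,0.0484749732744901,3
spleen,              72,1.85966408525698,0.144080275315654,3
tumor,               4,2.34912887576316,0.246629031803448,3
tumor,              24,10.8673394309074,1.00634883560421,3
tumor,              48,12.7084344323204,0.526505975523543,3
tumor,              72,12.2550537326158,1.67756599248305,3
whole_body,               4,3.60427288111605,0.239294282583091,3
whole_body,              24,2.65458207283845,0.14378064811007,3
whole_body,              48,2.23650624158518,0.220740350939438,3
whole_body,              72,1.79814398559333,0.171816867209771,3
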