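# shared fixtures, built in code

# tiny two-organ phantom whose organs exhaust the body mass (no carcass)
tiny_phantom <- function() {
  phantom(c(liver = 2, kidneys = 4, spleen = 4), body_mass_g = 10)
}

# a decayed monoexponential source curve A0 %IA, effective half-life hl_h,
# sampled with step dt_h on [0, t_max]; physical_decay label arbitrary
mono_curve <- function(A0 = 10, hl_h = 50, dt_h = 0.1, t_max = 300,
                       organ = "liver", decay_label = "Lu-177") {
  t <- seq(0, t_max, by = dt_h)
  source_curves <- getFromNamespace("source_curves", "mirdose")
  source_curves(rep(organ, length(t)), t, A0 * exp(-log(2) / hl_h * t),
                physical_decay = decay_label)
}

make_curves <- function(organ, time_h, pct_ia, physical_decay = NA_character_,
                        provenance = "delineated") {
  source_curves <- getFromNamespace("source_curves", "mirdose")
  source_curves(organ, time_h, pct_ia, provenance,
                physical_decay = physical_decay)
}

# random small S-matrix + cumulated activities for oracle comparisons
random_dose_instance <- function(n_organs, seed) {
  set.seed(seed)
  organs <- paste0("org", seq_len(n_organs))
  S <- matrix(runif(n_organs^2, 0, 0.5), n_organs, n_organs,
              dimnames = list(organs, organs))
  a <- runif(n_organs, 0, 20)
  names(a) <- organs
  list(S = S, a = a, organs = organs)
}
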