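# Independent alignment oracle: exhaustive enumeration over all monotone
# label matchings. Used to pin the DP against a path it shares nothing with.

score_matching <- function(ref, mol, ri, mi, s, params) {
  k <- length(ri)
  sc <- k * params$match_reward
  if (k > 1) {
    dref <- diff(ref[ri])
    dmol <- diff(mol[mi]) / s
    sc <- sc -
      sum((dref - dmol)^2 / (2 * params$sizing_sd_kb_per_sqrt_kb^2 * dref)) -
      params$miss_penalty * sum(diff(ri) - 1) -
      params$false_penalty * sum(diff(mi) - 1)
  }
  sc
}

brute_force_score <- function(ref, mol, s, params) {
  n <- length(ref); m <- length(mol)
  best <- -Inf
  for (k in seq_len(min(n, m))) {
    ri_all <- utils::combn(n, k)
    mi_all <- utils::combn(m, k)
    for (a in seq_len(ncol(ri_all))) {
      ri <- ri_all[, a]
      for (b in seq_len(ncol(mi_all))) {
        sc <- score_matching(ref, mol, ri, mi_all[, b], s, params)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

random_align_instance <- function() {
  n <- sample(3:8, 1)
  m <- sample(3:8, 1)
  list(ref = cumsum(runif(n, 2, 12)),
       mol = cumsum(runif(m, 2, 12)),
       s = runif(1, 0.95, 1.05))
}
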