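# Independent oracles. These deliberately avoid the code paths they check:
# the FCLS oracle is a multiresolution exhaustive search over the
# probability simplex, and the Wilcoxon oracle enumerates group labelings
# directly.

# all 4-part compositions of `div` units -> simplex grid with step 1/div
simplex_grid <- function(div) {
  pts <- list()
  i <- 1
  for (a in 0:div) for (b in 0:(div - a)) {
    cc <- 0:(div - a - b)
    pts[[i]] <- cbind(a, b, cc, div - a - b - cc)
    i <- i + 1
  }
  do.call(rbind, pts) / div
}

# Exhaustive multiresolution grid search for min ||s - M f|| over the
# simplex, refined from step 0.05 down to `step`. A beam of the best
# candidates is carried between levels because ill-conditioned libraries
# have long flat valleys: refining around the single best coarse point
# can land on a suboptimal lattice point even though the objective is
# convex.
fcls_oracle <- function(spectrum, M, step = 1e-3, beam = 30) {
  MtM <- crossprod(M)
  Mts <- drop(crossprod(M, spectrum))
  obj <- function(F)  # ||s - M f||^2 up to the constant ||s||^2
    rowSums((F %*% MtM) * F) - 2 * drop(F %*% Mts)
  keep_best <- function(cand, k)
    cand[order(obj(cand))[seq_len(min(k, nrow(cand)))], , drop = FALSE]
  G <- keep_best(simplex_grid(20), beam)   # step 0.05
  h <- 0.05
  while (h > step) {
    hn <- max(h / 5, step)
    d <- seq(-5 * hn, 5 * hn, by = hn)
    loc <- as.matrix(expand.grid(d, d, d))
    loc <- cbind(loc, -rowSums(loc))
    nb <- nrow(G); no <- nrow(loc)
    cand <- G[rep(seq_len(nb), each = no), , drop = FALSE] +
      loc[rep(seq_len(no), nb), , drop = FALSE]
    cand <- cand[rowSums(cand < -1e-12) == 0, , drop = FALSE]
    G <- keep_best(cand, beam)
    h <- hn
  }
  G[1, ]
}

# Two-sided exact Mann-Whitney p by direct enumeration of all
# choose(n1+n2, n1) assignments of the pooled values to group 1.
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  ustat <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- ustat(seq_len(n1))
  all_u <- combn(length(pooled), n1, ustat)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(p, 1)
}
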