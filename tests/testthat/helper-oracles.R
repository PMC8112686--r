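# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# O(N^2)-style direct-lag autocorrelation with unbiased normalization,
# matching the definition G(k) = <dI dI_k>/(L-k)/<I>^2 on one record.
direct_acf_oracle <- function(x, nlag) {
  mu <- mean(x)
  d <- x - mu
  L <- length(x)
  vapply(seq_len(nlag), function(k) {
    sum(d[seq_len(L - k)] * d[(k + 1):L]) / (L - k)
  }, numeric(1)) / mu^2
}

# Real-space quadrature of the Boussinesq/Cerruti surface response:
# u_i(r) = (1+nu)/(pi E r^3) [ (1-nu) r^2 d_ij + nu r_i r_j ] F_j,
# integrated over each elliptical patch with sub-cell spacing hq (um).
boussinesq_oracle <- function(px, py, scene, hq = 0.04) {
  e <- scene$substrate$e_pa
  nu <- scene$substrate$nu
  u <- 0; v <- 0
  for (i in seq_len(nrow(scene$patches))) {
    p <- scene$patches[i, ]
    rmax <- max(p$a, p$b)
    qs <- seq(-rmax, rmax, by = hq)
    qg <- expand.grid(qx = qs, qy = qs)
    xr <- qg$qx * cos(p$theta) + qg$qy * sin(p$theta)
    yr <- -qg$qx * sin(p$theta) + qg$qy * cos(p$theta)
    keep <- (xr / p$a)^2 + (yr / p$b)^2 <= 1
    qx <- p$x + qg$qx[keep]
    qy <- p$y + qg$qy[keep]
    fx <- p$stress_pa * p$dx * hq^2
    fy <- p$stress_pa * p$dy * hq^2
    rx <- px - qx; ry <- py - qy
    r2 <- rx^2 + ry^2
    pref <- (1 + nu) / (pi * e * r2^1.5)
    u <- u + sum(pref * ((1 - nu) * r2 * fx + nu * rx * (rx * fx + ry * fy)))
    v <- v + sum(pref * ((1 - nu) * r2 * fy + nu * ry * (rx * fx + ry * fy)))
  }
  c(u, v)
}

# Exhaustive-enumeration two-sided Mann-Whitney p-value (no ties).
mann_whitney_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_of <- function(idx_a) sum(ranks0[idx_a]) - na * (na + 1) / 2
  ranks0 <- seq_len(na + nb)  # enumeration permutes rank positions
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) sum(ranks0[ix]) - na * (na + 1) / 2)
  centre <- na * nb / 2
  mean(abs(us - centre) >= abs(u_obs - centre))
}

# A balanced two-patch dipole scene with exactly known patch geometry, used
# by the forward-model oracle comparison.
dipole_scene <- function(extent_um = 72, e_pa = 3.4e3) {
  sc <- make_traction_scene(n_patches = 2, extent_um = extent_um,
                            cell_radius_um = 12, stress_jitter = 0,
                            substrate = elastic_substrate(e_pa), seed = 7)
  p <- sc$patches
  p$x <- c(12, 24); p$y <- c(18, 18)
  p$a <- 1.2; p$b <- 0.66; p$theta <- 0
  p$stress_pa <- 500
  p$dx <- c(1, -1); p$dy <- c(0, 0)
  sc$patches <- p
  sc
}
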