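# Independent oracles and small fixture builders used across the suite.

# brute-force all-pairs minimum voxel-centre distance (mm)
brute_min_dist <- function(A, B) {
  pa <- sweep(which(A$mask, arr.ind = TRUE) - 1, 2, A$spacing, "*")
  pb <- sweep(which(B$mask, arr.ind = TRUE) - 1, 2, B$spacing, "*")
  best <- Inf
  for (i in seq_len(nrow(pa)))
    best <- min(best, min(colSums((t(pb) - pa[i, ])^2)))
  sqrt(best)
}

# explicit normal-equations OLS: coefficients and R^2
normal_eq <- function(X, y) {
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(Xm), crossprod(Xm, y))
  fittedv <- Xm %*% beta
  ss_res <- sum((y - fittedv)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(coefficients = as.numeric(beta), r_squared = 1 - ss_res / ss_tot)
}

# analytic sphere mask centred on the lattice
sphere_mask <- function(radius_mm, spacing, margin_vox = 2, name = "sphere",
                        centre_offset = c(0, 0, 0)) {
  n <- ceiling(2 * radius_mm / spacing) + 2 * margin_vox + 1
  ctr <- (n - 1) / 2 * spacing + centre_offset
  z <- (seq_len(n) - 1) * spacing
  g <- expand.grid(z = z, y = z, x = z)
  m <- array((g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <=
               radius_mm^2, c(n, n, n))
  structure_mask(name, m, rep(spacing, 3))
}

# one small phantom + hybrid dose, computed once per test run
small_phantom_env <- new.env()
small_phantom_case <- function() {
  if (is.null(small_phantom_env$case)) {
    spec <- phantom_spec(shape = c(72, 46, 60), spacing = c(4.5, 4.5, 4.5),
                         seed = 11L)
    st <- make_phantom(spec)
    comp <- make_dose(st, dose_model_spec("C&S"))
    hyb <- hybrid_plan_dose(comp$cfrt, comp$boost, comp$cfrt_scheme,
                            comp$boost_scheme, alpha_beta_map(), st)
    small_phantom_env$case <- list(spec = spec, structures = st,
                                   components = comp, hybrid = hyb)
  }
  small_phantom_env$case
}

# random blob mask on a small lattice (for distance/DVH oracles)
random_blob <- function(dims, spacing, n_seeds, seed, name = "blob") {
  set.seed(seed)
  m <- array(FALSE, dims)
  idx <- cbind(sample(dims[1], n_seeds, TRUE), sample(dims[2], n_seeds, TRUE),
               sample(dims[3], n_seeds, TRUE))
  m[idx] <- TRUE
  structure_mask(name, m, spacing)
}
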