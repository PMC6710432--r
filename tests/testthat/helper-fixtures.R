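# Shared fixtures and independent oracles for the test suite. Heavy objects
# are memoized within one test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  val <- .fixture_cache[[key]]
  if (is.null(val)) {
    val <- force(expr)
    .fixture_cache[[key]] <- val
  }
  val
}

# small phantom (16^3, 6 regions) used by most module tests
small_atlas <- function() memo("small_atlas", {
  build_phantom_atlas(c(16L, 16L, 16L), n_regions = 6L, seed = 3)
})

small_effects <- function(amplitude = 0.1) {
  stats::setNames(c(amplitude, amplitude, -amplitude, -amplitude),
                  c(1, 2, 4, 5))
}

small_cohort <- function(seed = 11) memo(paste0("small_cohort_", seed), {
  atlas <- small_atlas()
  truth <- make_ground_truth_pattern(atlas, small_effects())
  generate_cohort(atlas, truth, seed = seed)
})

small_features <- function(seed = 11) memo(paste0("small_fm_", seed), {
  feature_matrix(small_cohort(seed))
})

# default full-scale phantom (32^3, 15 regions) for the acceptance suite
default_phantom <- function(seed = 42) memo(paste0("phantom_", seed), {
  atlas <- build_phantom_atlas(c(32L, 32L, 32L), n_regions = 15L,
                               seed = seed)
  truth <- make_ground_truth_pattern(atlas, default_region_effects())
  cohort <- generate_cohort(atlas, truth, seed = seed)
  fm <- feature_matrix(cohort)
  list(atlas = atlas, truth = truth, cohort = cohort, fm = fm)
})

derived_pattern <- function(mode = "classification", seed = 42) {
  memo(paste0("pattern_", mode, "_", seed), {
    ph <- default_phantom(seed)
    pat <- metabolic_pattern(ph$fm, timepoint = "w9", mode = mode,
                             seed = 1)
    h <- pat$hyperparameters
    lo <- loocv_pattern(ph$fm, timepoint = "w9", mode = mode, C = h$C,
                        kernel_scale = h$kernel_scale, epsilon = h$epsilon)
    proj <- longitudinal_projection(pat, ph$fm, loocv = lo)
    list(pattern = pat, loocv = lo, projection = proj)
  })
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# ---- independent oracles -------------------------------------------------

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n_a + n_b, n_a) group assignments (tie-free inputs)
wilcoxon_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2L, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# generic QP solution of the shared SMO dual via kernlab::ipop, with an
# adaptive ridge for rank-deficient Hessians; returns NULL if the interior
# point method cannot solve the instance
ipop_dual_objective <- function(K, y, p, C) {
  H <- tcrossprod(y) * K
  for (lam in c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5)) {
    sv <- try(kernlab::ipop(c = p, H = H + diag(lam, nrow(H)),
                            A = matrix(y, 1), b = 0,
                            l = rep(0, length(y)), u = rep(C, length(y)),
                            r = 0, sigf = 9, maxiter = 300),
              silent = TRUE)
    if (!inherits(sv, "try-error")) {
      z <- kernlab::primal(sv)
      # objective of the unridged problem at the oracle's feasible point
      return(0.5 * sum((z * y) * (K %*% (z * y))) + sum(p * z))
    }
  }
  NULL
}

mbp_dual_objective <- function(model, features) {
  getFromNamespace("dual_objective", "mbpattern")(model, features)
}
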