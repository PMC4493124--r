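`%||%` <- function(x, y) if (is.null(x)) y else x

# heavier simulated objects are built once per test run and shared
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

# quick single-chromosome (by default) genotype panel around a code matrix
toy_geno <- function(codes, cM = NULL, bp = NULL, chrom = NULL) {
  m <- ncol(codes)
  map <- genetic_map(data.frame(
    marker = paste0("t", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    cM = cM %||% seq(0, by = 10, length.out = m),
    bp = bp %||% seq(1e5, by = 1e5, length.out = m)
  ))
  genotypes(codes, map)
}

# moderate-size study populations for unit tests (full-size ones live in
# the acceptance tests)
syn4_small <- function() {
  cached("syn4_small", sim_gs_study(
    syn4_design(n_lines = 100), n_markers = 300,
    trait_model(n_qtl = 17, target_Vg = 1074.74, target_h2 = 0.81, n_reps = 4),
    seed = 101))
}

syn10_small <- function() {
  cached("syn10_small", sim_gs_study(
    syn10_design(n_lines = 100), n_markers = 300,
    trait_model(n_qtl = 17, target_Vg = 895.96, target_h2 = 0.79, n_reps = 4),
    seed = 202))
}

# full-size analogues of the two study populations, shared by the
# acceptance checks
syn4_full <- function() {
  cached("syn4_full", sim_gs_study(
    syn4_design(), n_markers = 1339,
    trait_model(n_qtl = 17, target_Vg = 1074.74, target_h2 = 0.81, n_reps = 4),
    seed = 1001))
}

syn10_full <- function() {
  cached("syn10_full", sim_gs_study(
    syn10_design(), n_markers = 6611,
    trait_model(n_qtl = 17, target_Vg = 895.96, target_h2 = 0.79, n_reps = 4),
    seed = 2002))
}

mixed_varcomp <- function() variance_components(Vg = 1022.71, Ve = 1022.71,
                                                n_reps = 4)
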