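# shared fixtures: all data are generated in code, nothing is stored

small_design <- function(K = 6, a = 3, Tn = 4, V = 5, seed = 11) {
  generate_design(design_spec(K, a, Tn, V, seed = seed))
}

paper_scale_design <- function(V = 30, seed = 7) {
  generate_design(design_spec(16, 4, 12, V, seed = seed))
}

# homogeneous population with a fixed spread of utilities
homogeneous_pop <- function(design, n = 100, sigma = 0, seed = 21,
                            u = NULL) {
  K <- design$spec$n_items
  if (is.null(u)) {
    u <- seq(1.2, -1.2, length.out = K)
    u <- u - mean(u)
  }
  simulate_population(
    population_spec(n, 1, class_utilities = matrix(u, K), sigma = sigma,
                    seed = seed),
    design)
}

# two-respondent hand-written response table on a small design
toy_records <- function(design) {
  Tn <- design$spec$n_tasks
  recs <- do.call(rbind, lapply(c("a", "b"), function(id) {
    v <- if (id == "a") 1L else 2L
    data.frame(respondent_id = id, version = v, task = seq_len(Tn),
               best = design$versions[[v]][, 1L],
               worst = design$versions[[v]][, 2L])
  }))
  recs
}
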