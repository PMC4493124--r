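test_that("the scenario table pairs training and validation sources correctly", {
  sc <- gs_scenarios()
  expect_equal(nrow(sc), 7)
  expect_equal(sc$type, c("within", "within", "between", "between",
                          "across", "across", "across"))
  expect_equal(sc$training[3], "pop_a")
  expect_equal(sc$validation[3], "pop_b")
  expect_equal(sc$training[5:7], rep("mixed", 3))
})

test_that("sample_marker_set returns the full panel at n_m = panel size", {
  map <- base_genome_map(120, n_chr = 4, total_cM = 400)
  expect_equal(sample_marker_set(map, 120, seed = 1), map$marker)
  picked <- sample_marker_set(map, 30, seed = 2)
  expect_equal(length(picked), 30)
  expect_false(any(duplicated(picked)))
  # returned in map order
  expect_equal(picked, map$marker[sort(match(picked, map$marker))])
  expect_error(sample_marker_set(map, 200), "exceeds")
  expect_warning(sample_marker_set(map, 3, seed = 3), "uncovered")
})

test_that("stratified marker draws beat simple random sampling on max gap", {
  map <- base_genome_map(1000, n_chr = 1, total_cM = 1000)
  n_m <- 50
  set.seed(21)
  wins <- 0L
  trials <- 400
  for (i in seq_len(trials)) {
    strat <- sample_marker_set(map, n_m)
    g_strat <- max(diff(map$cM[match(strat, map$marker)]))
    srs <- sort(sample(seq_len(1000), n_m))
    g_srs <- max(diff(map$cM[srs]))
    if (g_strat < g_srs) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.99)
})

test_that("splits are disjoint and sized per scenario", {
  lines_a <- paste0("A", 1:194)
  lines_b <- paste0("B", 1:244)
  set.seed(31)
  for (sid in 1:7) {
    for (np in c(30, 60)) {
      sp <- build_split(sid, lines_a, lines_b, np)
      expect_length(intersect(sp$train, sp$validation), 0)
      expect_length(sp$train, np)
    }
  }
  # within-population: 180 training lines from a 194-line panel leave 14
  sp1 <- build_split(1, lines_a, lines_b, 180, seed = 5)
  expect_length(sp1$validation, 14)
  # between: validation is the entire other population
  sp3 <- build_split(3, lines_a, lines_b, 60, seed = 6)
  expect_setequal(sp3$validation, lines_b)
  # across: equal numbers from each population
  sp5 <- build_split(5, lines_a, lines_b, 60, seed = 7)
  expect_equal(sum(grepl("^A", sp5$train)), 30)
  expect_equal(sum(grepl("^B", sp5$train)), 30)
  expect_setequal(sp5$validation,
                  setdiff(c(lines_a, lines_b), sp5$train))
  # scenario 6 validates only the pop_a remainder
  sp6 <- build_split(6, lines_a, lines_b, 60, seed = 8)
  expect_true(all(grepl("^A", sp6$validation)))

  expect_error(build_split(1, lines_a, lines_b, 194), "empty validation")
  expect_error(build_split(5, lines_a, lines_b, 61), "even")
})

test_that("run_grid produces the expected table shape deterministically", {
  st <- syn4_small()
  pheno <- line_means(st$trait$plots)
  data <- list(pop_a = list(geno = st$geno, pheno = pheno))
  grid <- grid_spec(marker_counts = 50, training_sizes = 40, n_repeats = 2,
                    seed = 11)
  sc <- gs_scenarios()[1, ]
  tab <- run_grid(data, sc, grid, mixed_varcomp())
  expect_equal(nrow(tab), 2)
  expect_equal(tab$rep, 1:2)
  expect_true(all(is.finite(tab$r_mg)))
  expect_equal(nrow(summarise_accuracy(tab)), 1)

  tab2 <- run_grid(data, sc, grid, mixed_varcomp())
  expect_identical(as.data.frame(tab), as.data.frame(tab2))

  # r_MG = r_MP / h row by row
  expect_equal(tab$r_mg, tab$r_mp / sqrt(0.80))

  wide <- accuracy_matrix(tab, 1)
  expect_equal(names(wide), c("n_p", "N_M_50"))
})

test_that("run_grid covers mixed scenarios over a combined panel", {
  st4 <- syn4_small()
  st10 <- syn10_small()
  # same base map: panels can be stacked; relabel lines to keep ids unique
  g10 <- st10$geno
  rownames(g10$codes) <- paste0("X", rownames(g10$codes))
  ph10 <- line_means(st10$trait$plots)
  ph10$line <- paste0("X", ph10$line)
  data <- list(pop_a = list(geno = g10, pheno = ph10),
               pop_b = list(geno = st4$geno,
                            pheno = line_means(st4$trait$plots)))
  grid <- grid_spec(marker_counts = 60, training_sizes = 40, n_repeats = 2,
                    seed = 13)
  tab <- run_grid(data, gs_scenarios()[c(3, 5), ], grid, mixed_varcomp())
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$scenario), c(3, 5))
  expect_true(all(is.finite(tab$r_mg)))
})

test_that("Bonferroni LSD reduces to the pooled t-test for two cells", {
  tab <- structure(
    tibble::tibble(scenario = 1L,
                   n_p = rep(c(30L, 60L), each = 3),
                   n_m = 100L,
                   rep = rep(1:3, 2),
                   r_mp = NA_real_,
                   r_mg = c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7)),
    class = c("gs_accuracy", class(tibble::tibble())))
  res <- lsd_bonferroni(tab, alpha = 0.05)
  expect_equal(res$lsd$mse, 0.01)
  expect_equal(res$lsd$alpha_adj, 0.05)      # k = 2: no adjustment
  expect_equal(res$lsd$lsd, qt(0.975, 4) * sqrt(2 * 0.01 / 3))
  # matches a direct pooled two-sample t-test decision
  tt <- t.test(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3), var.equal = TRUE)
  expect_equal(tt$p.value < 0.05, res$pairs$significant)
  expect_equal(res$pairs$diff, 0.4, ignore_attr = TRUE)
})

test_that("identical cells are never flagged and k scales the adjustment", {
  tab <- structure(
    tibble::tibble(scenario = 1L,
                   n_p = rep(c(30L, 60L, 90L), each = 4),
                   n_m = 100L,
                   rep = rep(1:4, 3),
                   r_mp = NA_real_,
                   r_mg = rep(0.5, 12)),
    class = c("gs_accuracy", class(tibble::tibble())))
  res <- lsd_bonferroni(tab)
  expect_false(any(res$pairs$significant))
  expect_equal(res$lsd$alpha_adj, 0.05 / choose(3, 2))

  expect_error(lsd_bonferroni(tab[1:4, ]), ">= 2 cells")
})
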