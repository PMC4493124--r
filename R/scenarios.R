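#' The seven training/validation scenarios
#'
#' The canonical scenario table for two intermated populations, here
#' labelled `pop_a` (e.g. a Syn10-like panel) and `pop_b` (Syn4-like):
#' within-population prediction (1: a/a, 2: b/b), between-population
#' (3: train a, validate b; 4: train b, validate a) and across-population
#' with a mixed training set (5: validate remainders of both; 6: validate
#' pop_a remainder; 7: validate pop_b remainder). Training and validation
#' sets are always disjoint.
#'
#' @return tibble with columns `scenario`, `training`, `validation`,
#'   `type`.
#' @export
gs_scenarios <- function() {
  tibble(
    scenario = 1:7,
    training = c("pop_a", "pop_b", "pop_a", "pop_b", "mixed", "mixed", "mixed"),
    validation = c("pop_a", "pop_b", "pop_b", "pop_a", "mixed", "pop_a", "pop_b"),
    type = c("within", "within", "between", "between",
             "across", "across", "across")
  )
}

#' Evenly distributed random marker set
#'
#' Draws `n_m` distinct markers with an even distribution across the
#' genetic map: the genome's cumulative cM axis is cut into `n_m`
#' equal-width strata and one marker is drawn uniformly within each
#' stratum; strata containing no (remaining) marker are served by the
#' nearest stratum that still has unchosen markers.
#'
#' @param map a `gs_map`.
#' @param n_m marker-set size (`n_m` equal to the panel size returns the
#'   full panel).
#' @param seed optional integer seed.
#' @return character vector of `n_m` marker ids in map order.
#' @export
sample_marker_set <- function(map, n_m, seed = NULL) {
  total_markers <- nrow(map)
  if (n_m > total_markers) abort("n_m exceeds the number of markers")
  if (!is.null(seed)) set.seed(seed)
  n_chr <- length(unique(map$chrom))
  if (n_m < n_chr) {
    warn("marker set smaller than the number of chromosomes; some chromosomes will be uncovered")
  }
  if (n_m == total_markers) return(map$marker)

  # cumulative genetic position across chromosomes
  spans <- tapply(map$cM, map$chrom, function(x) max(x) - min(x))
  chroms <- as.integer(names(spans))
  offset <- setNames(cumsum(c(0, head(as.numeric(spans), -1))), chroms)
  mins <- tapply(map$cM, map$chrom, min)
  pos <- offset[as.character(map$chrom)] +
    (map$cM - mins[as.character(map$chrom)])
  total <- sum(spans)

  edges <- seq(0, total, length.out = n_m + 1)
  stratum <- pmin(pmax(findInterval(pos, edges, rightmost.closed = TRUE), 1), n_m)

  chosen <- integer(0)
  available <- rep(TRUE, total_markers)
  members <- split(seq_len(total_markers), factor(stratum, levels = seq_len(n_m)))
  empty <- integer(0)
  for (s in seq_len(n_m)) {
    cand <- members[[s]]
    cand <- cand[available[cand]]
    if (length(cand) == 0) {
      empty <- c(empty, s)
      next
    }
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    chosen <- c(chosen, pick)
    available[pick] <- FALSE
  }
  for (s in empty) {
    # nearest stratum (by index) that still has available markers
    stratum_has <- which(purrr::map_lgl(members, function(ix) any(available[ix])))
    if (length(stratum_has) == 0) break
    near <- stratum_has[which.min(abs(stratum_has - s))]
    cand <- members[[near]]
    cand <- cand[available[cand]]
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    chosen <- c(chosen, pick)
    available[pick] <- FALSE
  }
  map$marker[sort(chosen)]
}

#' Split lines into training and validation sets for a scenario
#'
#' Within-population scenarios draw `n_p` random training lines from the
#' population and validate on its remainder; between-population scenarios
#' validate on the entire other population; across-population scenarios
#' draw `n_p / 2` lines from each population and validate on the pooled
#' (or named-population) remainder.
#'
#' @param scenario one row of [gs_scenarios()] (or a scenario id 1-7).
#' @param lines_a,lines_b character vectors of line ids of the two
#'   populations.
#' @param n_p training-set size (even for mixed training).
#' @param seed optional integer seed.
#' @return list with character vectors `train` and `validation` (disjoint).
#' @export
build_split <- function(scenario, lines_a, lines_b, n_p, seed = NULL) {
  if (is.numeric(scenario)) {
    scenario <- gs_scenarios()[gs_scenarios()$scenario == scenario, ]
  }
  stopifnot(nrow(scenario) == 1)
  if (!is.null(seed)) set.seed(seed)
  pools <- list(pop_a = lines_a, pop_b = lines_b)

  if (scenario$training == "mixed") {
    if (n_p %% 2 != 0) abort("mixed training requires an even n_p")
    half <- n_p / 2
    if (half >= length(lines_a) || half >= length(lines_b)) {
      abort("n_p too large for the source populations")
    }
    tr_a <- sample(lines_a, half)
    tr_b <- sample(lines_b, half)
    train <- c(tr_a, tr_b)
    validation <- switch(scenario$validation,
      mixed = c(setdiff(lines_a, tr_a), setdiff(lines_b, tr_b)),
      pop_a = setdiff(lines_a, tr_a),
      pop_b = setdiff(lines_b, tr_b)
    )
  } else {
    src <- pools[[scenario$training]]
    if (scenario$type == "within" && n_p >= length(src)) {
      abort("n_p >= population size leaves an empty validation set")
    }
    if (n_p > length(src)) abort("n_p exceeds the training population size")
    train <- sample(src, n_p)
    validation <- if (scenario$type == "within") {
      setdiff(src, train)
    } else {
      pools[[scenario$validation]]
    }
  }
  list(train = train, validation = validation)
}

#' Grid specification for scenario runs
#'
#' @param marker_counts marker-set sizes (capped at the panel size by
#'   [run_grid()]).
#' @param training_sizes training-population sizes.
#' @param n_repeats independent repeats per grid cell.
#' @param seed master seed; per-repeat seeds are derived from it so any
#'   repeat is reproducible in isolation.
#' @return a `gs_grid` list.
#' @export
grid_spec <- function(marker_counts = c(100, 200, 400, 800, 1600, 3200),
                      training_sizes = seq(30, 180, by = 30),
                      n_repeats = 100, seed = 1) {
  stopifnot(all(marker_counts >= 1), all(training_sizes >= 2), n_repeats >= 1)
  structure(list(marker_counts = sort(unique(marker_counts)),
                 training_sizes = sort(unique(training_sizes)),
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "gs_grid")
}

# counter-based derived seed, kept below 2^31
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 69621) %% 2147483647L)
}

#' Run the scenario x training-size x marker-density grid
#'
#' For every combination of scenario, training size `N_P`, marker count
#' `N_M` and repeat: draw an evenly distributed marker set (independently
#' per repeat), split lines into disjoint training/validation sets, fit
#' RR-BLUP on the training line means, predict the validation lines and
#' record `r_MP` and `r_MG = r_MP / h`. Deterministic given the grid seed.
#'
#' @param data named list with elements `pop_a` and (unless only
#'   within-pop_a scenarios are run) `pop_b`, each a list with elements
#'   `geno` (`gs_geno`) and `pheno` (line means as from [line_means()]).
#'   For between/across scenarios both panels must share a marker panel.
#' @param scenarios subset of [gs_scenarios()] (default: all seven).
#' @param grid a `gs_grid`.
#' @param var a `gs_varcomp` used for lambda and for h in `r_MG` (the
#'   mixed-population estimates in the canonical analysis).
#' @return a `gs_accuracy` tibble: `scenario`, `n_p`, `n_m`, `rep`,
#'   `r_mp`, `r_mg`; skipped repeats (fewer than 3 usable validation
#'   lines) are recorded in attribute `skipped`.
#' @export
run_grid <- function(data, scenarios = gs_scenarios(), grid = grid_spec(),
                     var) {
  stopifnot(inherits(grid, "gs_grid"), inherits(var, "gs_varcomp"))
  pop_a <- data$pop_a
  pop_b <- data$pop_b
  lines_a <- if (!is.null(pop_a)) line_ids(pop_a$geno) else character()
  lines_b <- if (!is.null(pop_b)) line_ids(pop_b$geno) else character()
  if (length(intersect(lines_a, lines_b)) > 0) {
    abort("pop_a and pop_b share line ids; relabel one population")
  }

  needs_b <- any(scenarios$training != "pop_a" | scenarios$validation != "pop_a")
  if (needs_b && is.null(pop_b)) abort("these scenarios require data$pop_b")

  if (!is.null(pop_b)) {
    geno_all <- bind_geno(pop_a$geno, pop_b$geno)
    pheno_all <- dplyr::bind_rows(pop_a$pheno, pop_b$pheno)
  } else {
    geno_all <- pop_a$geno
    pheno_all <- pop_a$pheno
  }
  if (anyNA(geno_all$codes)) abort("genotypes must be complete; impute first")
  y_all <- setNames(pheno_all$mean_value, pheno_all$line)
  panel_size <- ncol(geno_all$codes)
  marker_counts <- pmin(grid$marker_counts, panel_size)
  marker_counts <- sort(unique(marker_counts))

  rows <- list()
  skipped <- list()
  counter <- 0L
  for (si in seq_len(nrow(scenarios))) {
    sc <- scenarios[si, ]
    for (np in grid$training_sizes) {
      for (nm in marker_counts) {
        for (r in seq_len(grid$n_repeats)) {
          counter <- counter + 1L
          set.seed(derive_seed(grid$seed, counter))
          markers <- sample_marker_set(geno_all$map, nm)
          split <- build_split(sc, lines_a, lines_b, np)
          if (length(split$validation) < 3) {
            skipped[[length(skipped) + 1]] <-
              tibble(scenario = sc$scenario, n_p = np, n_m = nm, rep = r,
                     reason = "fewer than 3 validation lines")
            next
          }
          Xtr <- geno_all$codes[split$train, markers, drop = FALSE]
          fit <- fit_rrblup(Xtr, y_all[split$train], var)
          Xval <- geno_all$codes[split$validation, markers, drop = FALSE]
          pred <- predict(fit, Xval)
          acc <- accuracy(pred$gebv, y_all[split$validation], var$h2)
          rows[[length(rows) + 1]] <-
            tibble(scenario = sc$scenario, n_p = np, n_m = nm, rep = r,
                   r_mp = acc$r_MP, r_mg = acc$r_MG)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gs_accuracy", class(out))
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  attr(out, "h2") <- var$h2
  out
}

#' Summarise an accuracy table
#'
#' Mean, standard deviation and count of `r_MG` per (scenario, N_P, N_M)
#' cell; failed repeats are simply absent, never imputed.
#'
#' @param table a `gs_accuracy` tibble from [run_grid()].
#' @return tibble: scenario, n_p, n_m, mean_r_mg, sd_r_mg, n.
#' @export
summarise_accuracy <- function(table) {
  table |>
    dplyr::group_by(.data$scenario, .data$n_p, .data$n_m) |>
    dplyr::summarise(mean_r_mg = mean(.data$r_mg), sd_r_mg = sd(.data$r_mg),
                     n = dplyr::n(), .groups = "drop")
}

#' @describeIn summarise_accuracy per-scenario wide matrix of mean r_MG
#'   (rows N_P, columns N_M).
#' @param scenario_id which scenario to lay out.
#' @export
accuracy_matrix <- function(table, scenario_id) {
  summarise_accuracy(table) |>
    dplyr::filter(.data$scenario == scenario_id) |>
    dplyr::select("n_p", "n_m", "mean_r_mg") |>
    tidyr::pivot_wider(names_from = "n_m", values_from = "mean_r_mg",
                       names_prefix = "N_M_")
}

#' Bonferroni-adjusted least significant differences
#'
#' Within each scenario, a one-way ANOVA of repeat-level `r_MG` with the
#' (N_P, N_M) cell as factor gives the pooled error mean square; the LSD
#' at level `alpha` adjusted for all pairwise comparisons is
#' `t(1 - alpha' / 2, df_error) * sqrt(2 * MSE / n)` with
#' `alpha' = alpha / choose(k, 2)` for `k` cells and `n` the (harmonic
#' mean) repeat count. All cell pairs whose mean difference exceeds the
#' LSD are flagged.
#'
#' @param table a `gs_accuracy` tibble.
#' @param alpha familywise significance level.
#' @return list of class `gs_lsd`: `lsd` (tibble scenario, k, df, mse,
#'   alpha_adj, lsd) and `pairs` (tibble scenario, cell_1, cell_2, diff,
#'   significant).
#' @export
lsd_bonferroni <- function(table, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  lsd_rows <- list()
  pair_rows <- list()
  for (sc in unique(table$scenario)) {
    sub <- table[table$scenario == sc, ]
    sub$cell <- paste0("NP", sub$n_p, "_NM", sub$n_m)
    counts <- table(sub$cell)
    counts <- counts[counts >= 2]
    if (length(counts) < 2) {
      abort("need >= 2 cells with >= 2 repeats per scenario")
    }
    sub <- sub[sub$cell %in% names(counts), ]
    k <- length(counts)
    an <- suppressWarnings(anova(lm(r_mg ~ factor(cell), data = sub)))
    mse <- an$`Mean Sq`[2]
    df <- an$Df[2]
    if (length(unique(as.integer(counts))) > 1) {
      inform("unequal repeat counts: harmonic-mean n used in the LSD")
    }
    n_h <- k / sum(1 / as.numeric(counts))
    alpha_adj <- alpha / choose(k, 2)
    lsd <- qt(1 - alpha_adj / 2, df) * sqrt(2 * mse / n_h)
    lsd_rows[[length(lsd_rows) + 1]] <-
      tibble(scenario = sc, k = k, df = df, mse = mse,
             alpha_adj = alpha_adj, lsd = lsd)
    means <- tapply(sub$r_mg, sub$cell, mean)
    cmb <- utils::combn(names(means), 2)
    delta <- as.numeric(abs(means[cmb[1, ]] - means[cmb[2, ]]))
    pair_rows[[length(pair_rows) + 1]] <- tibble(
      scenario = sc,
      cell_1 = cmb[1, ], cell_2 = cmb[2, ],
      diff = delta,
      significant = delta > lsd
    )
  }
  structure(list(lsd = dplyr::bind_rows(lsd_rows),
                 pairs = dplyr::bind_rows(pair_rows)),
            class = "gs_lsd")
}

#' @export
print.gs_lsd <- function(x, ...) {
  cat("<gs_lsd> Bonferroni-adjusted least significant differences\n")
  print(x$lsd)
  cat(sum(x$pairs$significant), "of", nrow(x$pairs),
      "cell pairs significant\n")
  invisible(x)
}

#' @describeIn lsd_bonferroni pairwise comparison table.
#' @param x a `gs_lsd`.
#' @param ... unused.
#' @export
tidy.gs_lsd <- function(x, ...) x$pairs
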