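#' Describe an intermated biparental population design
#'
#' The designs emulated are maize IBM-style populations: two fully
#' homozygous founders are crossed, the F1 is selfed to an F2 pool, the
#' pool is randomly intermated for a number of generations, and lines are
#' then derived either as doubled haploids (one gamete doubled per line) or
#' as recombinant inbred lines (repeated selfing).
#'
#' @param n_lines number of derived lines.
#' @param intermating_generations generations of random mating after the F2
#'   (4 for a Syn4-like design, 10 for Syn10-like).
#' @param terminal `"DH"` or `"RIL"`.
#' @param selfing_generations selfing generations for RIL derivation
#'   (ignored for DH).
#' @param pool_size number of individuals maintained during intermating.
#' @return a `gs_design` list.
#' @export
population_design <- function(n_lines, intermating_generations,
                              terminal = c("DH", "RIL"),
                              selfing_generations = 6, pool_size = 200) {
  terminal <- match.arg(terminal)
  stopifnot(n_lines >= 2, intermating_generations >= 0, pool_size >= 2,
            selfing_generations >= 1)
  structure(list(n_lines = n_lines,
                 intermating_generations = intermating_generations,
                 terminal = terminal,
                 selfing_generations = selfing_generations,
                 pool_size = pool_size),
            class = "gs_design")
}

#' @describeIn population_design Syn4-like design: 244 RILs after 4
#'   generations of intermating.
#' @export
syn4_design <- function(n_lines = 244, pool_size = 200) {
  population_design(n_lines, 4, "RIL", selfing_generations = 6,
                    pool_size = pool_size)
}

#' @describeIn population_design Syn10-like design: 194 DH lines after 10
#'   generations of intermating.
#' @export
syn10_design <- function(n_lines = 194, pool_size = 200) {
  population_design(n_lines, 10, "DH", pool_size = pool_size)
}

# one meiosis over all chromosomes; h1/h2 are numeric vectors over map loci,
# chrom_index is a list of integer index vectors per chromosome.
# Crossovers: count ~ Poisson(length in Morgans), positions uniform on the
# cM axis (Haldane, no interference).
sim_gamete_impl <- function(h1, h2, map, chrom_index) {
  out <- h1
  for (idx in chrom_index) {
    pos <- map$cM[idx]
    L <- (pos[length(pos)] - pos[1]) / 100
    k <- if (L > 0) rpois(1, L) else 0L
    first_is_h1 <- runif(1) < 0.5
    if (k == 0) {
      if (!first_is_h1) out[idx] <- h2[idx]
      next
    }
    breaks <- sort(runif(k, min = pos[1], max = pos[length(pos)]))
    seg <- findInterval(pos, breaks)
    from_h1 <- (seg %% 2L == 0L) == first_is_h1
    out[idx] <- ifelse(from_h1, h1[idx], h2[idx])
  }
  out
}

chrom_index_list <- function(map) {
  unname(split(seq_len(nrow(map)), map$chrom))
}

#' Simulate one gamete from a parent's haplotype pair
#'
#' Meiosis under the Haldane model: the number of crossovers per chromosome
#' is Poisson with mean equal to the chromosome's genetic length in
#' Morgans, crossover positions are uniform on the cM axis, and there is no
#' interference. The map should be on the base (F2) scale.
#'
#' @param h1,h2 numeric vectors of allelic values at every map locus (the
#'   parent's two haplotypes).
#' @param map a `gs_map`.
#' @param seed optional integer seed.
#' @return a numeric vector: the recombinant gamete.
#' @export
sim_gamete <- function(h1, h2, map, seed = NULL) {
  if (nrow(map) == 0) abort("empty map")
  stopifnot(length(h1) == nrow(map), length(h2) == nrow(map))
  if (!is.null(seed)) set.seed(seed)
  sim_gamete_impl(h1, h2, map, chrom_index_list(map))
}

#' Simulate an intermated biparental population
#'
#' Founders are two fully homozygous inbreds carrying allele 0 and 2 at
#' every marker. The F1 is selfed to produce an F2 pool of
#' `design$pool_size` individuals; the pool is then randomly mated (no
#' selfing, parents drawn with replacement, one offspring per pairing) for
#' `design$intermating_generations` generations; finally each line is
#' derived as a doubled haploid (one gamete doubled) or by repeated selfing
#' with any residual heterozygous locus resolved by doubling one random
#' allele. The output is fully homozygous with codes in \{0, 2\}.
#'
#' @param design a `gs_design` (see [population_design()]).
#' @param base_map a `gs_map` on the base (F2) scale.
#' @param seed optional integer seed.
#' @param line_prefix prefix for generated line ids.
#' @return a `gs_geno`; note its map is the base map — the realized
#'   (expanded) map can be estimated with [estimate_expanded_map()].
#' @export
sim_population <- function(design, base_map, seed = NULL, line_prefix = "L") {
  stopifnot(inherits(design, "gs_design"), inherits(base_map, "gs_map"))
  if (!is.null(seed)) set.seed(seed)
  n_loci <- nrow(base_map)
  if (n_loci == 0) abort("empty map")
  ci <- chrom_index_list(base_map)
  pool <- design$pool_size

  f1_h1 <- rep(0, n_loci)
  f1_h2 <- rep(2, n_loci)

  # F2 pool: each individual from two independent F1 gametes
  H1 <- matrix(0, nrow = pool, ncol = n_loci)
  H2 <- matrix(0, nrow = pool, ncol = n_loci)
  for (i in seq_len(pool)) {
    H1[i, ] <- sim_gamete_impl(f1_h1, f1_h2, base_map, ci)
    H2[i, ] <- sim_gamete_impl(f1_h1, f1_h2, base_map, ci)
  }

  # random non-self intermating
  for (g in seq_len(design$intermating_generations)) {
    N1 <- matrix(0, nrow = pool, ncol = n_loci)
    N2 <- matrix(0, nrow = pool, ncol = n_loci)
    for (i in seq_len(pool)) {
      p <- sample.int(pool, 2, replace = FALSE)
      N1[i, ] <- sim_gamete_impl(H1[p[1], ], H2[p[1], ], base_map, ci)
      N2[i, ] <- sim_gamete_impl(H1[p[2], ], H2[p[2], ], base_map, ci)
    }
    H1 <- N1
    H2 <- N2
  }

  codes <- matrix(0, nrow = design$n_lines, ncol = n_loci)
  if (design$terminal == "DH") {
    for (i in seq_len(design$n_lines)) {
      p <- sample.int(pool, 1)
      codes[i, ] <- sim_gamete_impl(H1[p, ], H2[p, ], base_map, ci)
    }
  } else {
    for (i in seq_len(design$n_lines)) {
      p <- sample.int(pool, 1)
      h1 <- H1[p, ]
      h2 <- H2[p, ]
      for (s in seq_len(design$selfing_generations)) {
        n1 <- sim_gamete_impl(h1, h2, base_map, ci)
        n2 <- sim_gamete_impl(h1, h2, base_map, ci)
        h1 <- n1
        h2 <- n2
      }
      het <- h1 != h2
      if (any(het)) {
        keep_first <- runif(sum(het)) < 0.5
        h1[het] <- ifelse(keep_first, h1[het], h2[het])
      }
      codes[i, ] <- h1
    }
  }
  rownames(codes) <- paste0(line_prefix, seq_len(design$n_lines))
  genotypes(codes, base_map)
}

#' Describe an additive trait architecture
#'
#' @param n_qtl number of additive QTL.
#' @param target_Vg genetic variance of true breeding values across lines
#'   (trait units squared); breeding values are rescaled to hit it exactly.
#' @param target_h2 heritability on the line-mean basis, in (0, 1].
#' @param n_reps plots per line.
#' @param qtl_markers optional character vector of marker ids to use as QTL
#'   (default: drawn uniformly without replacement at simulation time).
#' @return a `gs_trait_model` list.
#' @export
trait_model <- function(n_qtl = 17, target_Vg = 1022.71, target_h2 = 0.80,
                        n_reps = 4, qtl_markers = NULL) {
  stopifnot(n_qtl >= 1, target_Vg >= 0, target_h2 > 0, target_h2 <= 1,
            n_reps >= 1)
  structure(list(n_qtl = n_qtl, target_Vg = target_Vg,
                 target_h2 = target_h2, n_reps = n_reps,
                 qtl_markers = qtl_markers),
            class = "gs_trait_model")
}

#' Simulate an additive trait with replicated plot phenotypes
#'
#' True breeding values are sums of QTL allele codes weighted by effects
#' drawn from a standard normal, centred and rescaled so that their sample
#' variance across lines equals `target_Vg` exactly. Plot residuals are
#' i.i.d. normal with variance `Ve = n_reps * Vg * (1 - h2) / h2`, the
#' value at which the expected line-mean heritability equals `target_h2`
#' with `n_reps` plots per line.
#'
#' @param geno a complete `gs_geno` supplying QTL genotypes.
#' @param model a `gs_trait_model`.
#' @param seed optional integer seed.
#' @return a `gs_trait` list: `tbv` (tibble line, tbv), `plots` (tibble
#'   line, replicate, value), `qtl` (tibble marker, effect), `Vg`, `Ve`,
#'   `h2`, `n_reps`.
#' @export
sim_trait <- function(geno, model, seed = NULL) {
  stopifnot(inherits(geno, "gs_geno"), inherits(model, "gs_trait_model"))
  if (!is.null(seed)) set.seed(seed)
  codes <- geno$codes
  if (anyNA(codes)) abort("genotypes must be complete; impute first")
  if (model$n_qtl > ncol(codes)) abort("n_qtl exceeds marker count")

  qtl <- model$qtl_markers %||%
    sample(colnames(codes), model$n_qtl, replace = FALSE)
  unknown <- setdiff(qtl, colnames(codes))
  if (length(unknown) > 0) {
    abort(paste0("QTL marker(s) not in panel: ", paste(head(unknown, 5), collapse = ", ")))
  }
  eff <- rnorm(length(qtl))
  tbv <- as.vector(codes[, qtl, drop = FALSE] %*% eff)
  v <- var(tbv)
  if (v > 0 && model$target_Vg > 0) {
    sc <- sqrt(model$target_Vg / v)
    eff <- eff * sc
    tbv <- tbv * sc
  } else {
    eff <- eff * 0
    tbv <- tbv * 0
  }
  tbv <- tbv - mean(tbv)
  vg <- var(tbv)

  ve <- model$n_reps * vg * (1 - model$target_h2) / model$target_h2
  n <- length(tbv)
  plots <- tibble(
    line = rep(rownames(codes), each = model$n_reps),
    replicate = rep(paste0("rep", seq_len(model$n_reps)), times = n),
    value = rep(tbv, each = model$n_reps) +
      rnorm(n * model$n_reps, sd = sqrt(ve))
  )
  structure(list(
    tbv = tibble(line = rownames(codes), tbv = tbv),
    plots = plots,
    qtl = tibble(marker = qtl, effect = eff),
    Vg = vg, Ve = ve, h2 = model$target_h2, n_reps = model$n_reps
  ), class = "gs_trait")
}

#' @export
print.gs_trait <- function(x, ...) {
  cat("<gs_trait> ", nrow(x$tbv), " lines, ", nrow(x$qtl), " QTL, Vg = ",
      signif(x$Vg, 6), ", Ve(plot) = ", signif(x$Ve, 6), ", target h2 = ",
      x$h2, ", ", x$n_reps, " plots/line\n", sep = "")
  invisible(x)
}

#' Simulate a full genomic-selection study population
#'
#' Convenience wrapper: builds a base genome map with `n_markers` panel
#' markers, draws `n_qtl` QTL positions uniformly on the genetic map
#' (inserted as extra loci between markers, so QTL are tagged by the panel
#' only through linkage disequilibrium), simulates the population at the
#' augmented map, computes the trait from the hidden QTL genotypes and
#' returns the panel without the QTL columns.
#'
#' @param design a `gs_design`.
#' @param n_markers size of the marker panel.
#' @param trait a `gs_trait_model` (QTL marker ids are chosen internally).
#' @param base_map optional pre-built panel map (default
#'   [base_genome_map()] with package defaults).
#' @param seed optional integer seed.
#' @return list with elements `geno` (panel `gs_geno`), `trait`
#'   (`gs_trait`), `qtl_geno` (`gs_geno` of QTL loci), `design`.
#' @export
sim_gs_study <- function(design, n_markers, trait = trait_model(),
                         base_map = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- base_map %||% base_genome_map(n_markers)

  # QTL positions uniform on the cumulative genetic map, off-panel
  spans <- tapply(map$cM, map$chrom, function(x) max(x) - min(x))
  chroms <- as.integer(names(spans))
  total <- sum(spans)
  u <- runif(trait$n_qtl) * total
  cum <- cumsum(spans)
  qchrom <- chroms[findInterval(u, c(0, cum), rightmost.closed = TRUE)]
  offset <- u - c(0, head(cum, -1))[match(qchrom, chroms)]
  qtl_rows <- purrr::map2(qchrom, offset, function(ch, off) {
    sub <- map[map$chrom == ch, ]
    cm <- min(sub$cM) + off
    bp <- round(stats::approx(sub$cM, sub$bp, xout = cm, ties = "ordered")$y)
    tibble(chrom = ch, cM = cm, bp = bp)
  }) |> dplyr::bind_rows()
  qtl_rows$marker <- paste0("qtl", seq_len(nrow(qtl_rows)))
  aug <- genetic_map(dplyr::bind_rows(as_tibble(map), qtl_rows))

  pop <- sim_population(design, aug)
  is_qtl <- grepl("^qtl", aug$marker) & aug$marker %in% qtl_rows$marker
  panel <- subset_geno(pop, markers = aug$marker[!is_qtl])
  qtl_geno <- subset_geno(pop, markers = aug$marker[is_qtl])

  tm <- trait
  tm$qtl_markers <- colnames(qtl_geno$codes)
  trait_real <- sim_trait(qtl_geno, tm)
  list(geno = panel, trait = trait_real, qtl_geno = qtl_geno, design = design)
}
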