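#' Simulation configuration for a synthetic methylation panel
#'
#' Defines the study conditions emulated by [simulatePanel()]: a gene panel
#' with probed windows around each TSS, bimodal baseline methylation,
#' case/control mean shifts with a directional (hyper/hypo) bias constant
#' within a gene, linear age effects, batch offsets, latent (cell-mixture
#' like) structure, beta-binomial overdispersed counts over negative-binomial
#' coverage, optional technical replicates and mean-shifted outlier samples.
#'
#' Effects are stated in percentage points of methylation and converted to
#' the logit scale at each cytosine's baseline, so planted values are
#' directly comparable to the pipeline's percent-change output.
#'
#' @param ... named overrides of the defaults listed below.
#' @return named list (class `pdm_simconfig`).
#' @section Defaults:
#' 100 genes x 20-80 cytosines, window 300 kb, 20 cases + 20 controls,
#' negative-binomial coverage (mean 80, size 8), baseline beta from a
#' Beta(2,10)/Beta(10,2)/Beta(5,5) mixture, 10% of genes affected with a
#' 10-point shift on 50% of their cytosines (70% hypermethylated), ages
#' 40-90 with 0.3 points/year at 10% of cytosines, 2 batches (SD 2 points),
#' 1 latent factor (SD 3 points), overdispersion rho 0.02.
#' @export
simConfig <- function(...) {
  cfg <- list(
    n_genes = 100L,
    cytosines_per_gene = c(20L, 80L),
    window_bp = 300000L,
    n_case = 20L,
    n_control = 20L,
    coverage_mean = 80,
    coverage_dispersion = 8,
    baseline_mix_weights = c(0.3, 0.3, 0.4),
    baseline_mix_shapes = list(c(2, 10), c(10, 2), c(5, 5)),
    frac_affected_genes = 0.1,
    frac_affected_cytosines = 0.5,
    effect_pct = 10,
    effect_pct_cv = 0.3,   # lognormal spread of per-cytosine |shift|, mean kept

    hyper_fraction = 0.7,
    effect_location = "anywhere",   # or "promoter"
    affected_pathway = NULL,        # e.g. "lysosome": restrict affected genes
    age_range = c(40, 90),
    frac_age_cytosines = 0.1,
    age_slope_pct_per_year = 0.3,
    age_placement = "independent",  # or "shared_with_case"
    n_batches = 2L,
    batch_sd = 2,
    batch_confounding = 0,  # shift in P(batch) between groups (2-batch case)
    n_latent_factors = 1L,
    latent_sd = 3,
    latent_mean = 2,   # cell-mixture factors shift global methylation level
    n_replicate_pairs = 0L,
    n_outlier_samples = 0L,
    outlier_shift_sd = 8,
    rho = 0.01,
    eps = 1e-3,
    cph_fraction = 0,
    seed = 1L,
    noise_seed = NULL   # when set, sampling noise streams use this seed so
                        # replication datasets share the planted truth
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  stopIfNot(!length(bad), "unknown sim config field(s): %s",
            paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  fr <- c("frac_affected_genes", "frac_affected_cytosines", "hyper_fraction",
          "frac_age_cytosines", "cph_fraction")
  for (f in fr)
    stopIfNot(cfg[[f]] >= 0 && cfg[[f]] <= 1, "'%s' must be in [0, 1]", f)
  stopIfNot(cfg$coverage_mean > 0, "coverage_mean must be > 0")
  stopIfNot(cfg$rho >= 0 && cfg$rho < 1, "rho must be in [0, 1)")
  class(cfg) <- c("pdm_simconfig", "list")
  cfg
}

## evaluate code under a fixed stream seed, restoring the caller's RNG state
withStream <- function(seed, stream, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv))
  set.seed(streamSeed(seed, stream))
  force(code)
}

## gene layout + annotation: non-overlapping windows, promoter-weighted sites
simLayout <- function(cfg) {
  withStream(cfg$seed, "layout", {
    n <- cfg$n_genes
    w <- cfg$window_bp
    chrom <- paste0("chr", (seq_len(n) - 1L) %% 5L + 1L)
    idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    tss <- as.integer(w + 1 + (idx_on_chrom - 1) * (2 * w + 100000))
    gene_id <- sprintf("G%03d", seq_len(n))
    ## pathway memberships: ~30% lysosome, ~30% autophagy, rest none
    pw_draw <- runif(n)
    pathways <- lapply(pw_draw, function(u)
      if (u < 0.3) "lysosome" else if (u < 0.6) "autophagy" else character())
    genes <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                        strand = "+", window_bp = w,
                        gwas_flag = FALSE, stringsAsFactors = FALSE)
    genes$pathways <- pathways
    mk <- function(lo, hi) GRanges(chrom, IRanges(pmax(tss + lo, 1L), tss + hi))
    ## element classes are kept disjoint (cgi as "orphan" islands away from
    ## the TSS) so specificity of element enrichment is testable
    elements <- GRangesList(
      promoter = mk(-1000L, 500L),
      cgi = mk(50000L, 51000L),
      exon = mk(501L, 2500L),
      intron = mk(2501L, 10000L),
      `1to5kb` = mk(-5000L, -1001L),
      intergenic = sort(c(mk(10001L, w), mk(-w, -5001L)))
    )
    ncs <- if (length(cfg$cytosines_per_gene) == 2)
      sample(cfg$cytosines_per_gene[1]:cfg$cytosines_per_gene[2], n, TRUE)
    else rep(as.integer(cfg$cytosines_per_gene), n)
    site_gene <- rep(seq_len(n), ncs)
    pos <- integer(length(site_gene))
    for (g in seq_len(n)) {
      sel <- which(site_gene == g)
      k <- length(sel)
      k_prom <- max(1L, round(0.2 * k))
      p1 <- sample((tss[g] - 1000L):(tss[g] + 500L), k_prom)
      p2 <- sample(setdiff(seq(tss[g] - w, tss[g] + w, by = 7L),
                           p1), k - k_prom)
      pos[sel] <- sort(c(p1, p2))
    }
    context <- rep("CpG", length(pos))
    if (cfg$cph_fraction > 0)
      context[runif(length(pos)) < cfg$cph_fraction] <- "CpH"
    list(genes = genes, elements = elements,
         keys = data.frame(chrom = chrom[site_gene], pos = pos,
                           strand = "+", context = context,
                           stringsAsFactors = FALSE),
         site_gene = gene_id[site_gene])
  })
}

#' Simulate a targeted methylation panel with known truth
#'
#' Per cytosine i and sample j the mean methylation is
#' \eqn{\mu_{ij} = \mathrm{clamp}(\mathrm{logistic}(\mathrm{logit}(b_i) +
#' s_i (\delta_i \mathrm{case}_j + \gamma_i \tilde a_j + \mathrm{batch}_{ij}
#' + \mathrm{latent}_{ij} + \mathrm{outlier}_j)), \epsilon, 1-\epsilon)}
#' with \eqn{s_i = 1 / (100\, b_i (1 - b_i))} the logit-scale equivalent of
#' one percentage point at baseline \eqn{b_i} and \eqn{\tilde a_j} the
#' mean-centred age.  Coverage is negative-binomial, methylated counts
#' beta-binomial with overdispersion `rho`.  Technical replicates redraw
#' counts at the same \eqn{\mu}; outlier samples receive a global mean shift
#' of `outlier_shift_sd` standard deviations of the sample means.  All draws
#' derive from `cfg$seed` through fixed per-stage streams, so the output is
#' fully reproducible and stage draws are mutually stable.
#'
#' @param cfg a [simConfig()] list.
#' @return list with elements `counts` ([MethylCountSet-class] including the
#'   sample sheet), `annotation` ([PanelAnnotation-class]), and `truth`
#'   (planted per-cytosine effects `delta` and `gamma` in percentage points,
#'   per-gene assignment, batch offsets, latent loadings and scores, outlier
#'   ids, clamped-cell fraction).
#' @examples
#' sim <- simulatePanel(simConfig(n_genes = 5, n_case = 4, n_control = 4,
#'                                seed = 7))
#' dim(methReads(sim$counts))
#' @export
simulatePanel <- function(cfg = simConfig()) {
  lay <- simLayout(cfg)
  G <- nrow(lay$keys)

  b <- withStream(cfg$seed, "baseline", {
    comp <- sample(length(cfg$baseline_mix_weights), G, TRUE,
                   prob = cfg$baseline_mix_weights)
    sh <- do.call(rbind, cfg$baseline_mix_shapes)[comp, , drop = FALSE]
    clamp(rbeta(G, sh[, 1], sh[, 2]), cfg$eps, 1 - cfg$eps)
  })

  eff <- withStream(cfg$seed, "effects", {
    gene_ids <- lay$genes$gene_id
    eligible <- gene_ids
    if (!is.null(cfg$affected_pathway)) {
      inpw <- vapply(lay$genes$pathways,
                     function(p) cfg$affected_pathway %in% p, TRUE)
      eligible <- gene_ids[inpw]
    }
    n_aff <- round(cfg$frac_affected_genes * cfg$n_genes)
    n_aff <- min(n_aff, length(eligible))
    aff_genes <- if (n_aff > 0) sample(eligible, n_aff) else character()
    sign_gene <- setNames(ifelse(runif(length(aff_genes)) < cfg$hyper_fraction,
                                 1, -1), aff_genes)
    delta <- numeric(G)
    for (g in aff_genes) {
      sel <- which(lay$site_gene == g)
      if (cfg$effect_location == "promoter") {
        gi <- match(g, gene_ids)
        tss <- lay$genes$tss[gi]
        p <- lay$keys$pos[sel]
        sel <- sel[p >= tss - 1000 & p <= tss + 500]
      }
      if (!length(sel)) next
      k <- max(1L, round(cfg$frac_affected_cytosines * length(sel)))
      ## plant only where the shift is expressible: a +10-point effect at a
      ## 95% baseline cannot exist, so such sites are never part of the truth
      room <- if (sign_gene[[g]] > 0) (1 - cfg$eps) - b[sel] else b[sel] - cfg$eps
      eligible <- sel[room * 100 >= cfg$effect_pct]
      if (!length(eligible)) next
      hit <- sample(eligible, min(k, length(eligible)))
      ## per-cytosine magnitudes are lognormal around effect_pct (mean
      ## preserved); real panels show heterogeneous, not constant, shifts
      nh <- length(hit)
      mag <- if (cfg$effect_pct_cv > 0) {
        sl <- sqrt(log(1 + cfg$effect_pct_cv^2))
        exp(rnorm(nh, -sl^2 / 2, sl))
      } else rep(1, nh)
      room_hit <- if (sign_gene[[g]] > 0) (1 - cfg$eps) - b[hit] else b[hit] - cfg$eps
      delta[hit] <- sign_gene[[g]] *
        pmin(cfg$effect_pct * mag, room_hit * 100)
    }
    gamma <- numeric(G)
    if (cfg$age_placement == "shared_with_case" && cfg$frac_age_cytosines > 0) {
      gamma <- delta * (cfg$age_slope_pct_per_year / cfg$effect_pct)
    } else if (cfg$frac_age_cytosines > 0) {
      n_age <- round(cfg$frac_age_cytosines * G)
      hit <- sample(G, n_age)
      gamma[hit] <- ifelse(runif(n_age) < 0.5, 1, -1) * cfg$age_slope_pct_per_year
    }
    batch_off <- matrix(0, G, cfg$n_batches)
    if (cfg$n_batches > 1)
      batch_off[, -1] <- rnorm(G * (cfg$n_batches - 1), 0, cfg$batch_sd)
    loadings <- matrix(rnorm(G * cfg$n_latent_factors, cfg$latent_mean,
                             cfg$latent_sd),
                       G, cfg$n_latent_factors)
    list(delta = delta, gamma = gamma, batch_off = batch_off,
         loadings = loadings)
  })

  nseed <- if (!is.null(cfg$noise_seed)) cfg$noise_seed else cfg$seed

  smp <- withStream(nseed, "samples", {
    n <- cfg$n_case + cfg$n_control
    sheet <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
      age = runif(n, cfg$age_range[1], cfg$age_range[2]),
      sex = sample(c("M", "F"), n, TRUE),
      pmi = runif(n, 5, 30),
      batch = paste0("B", if (cfg$n_batches == 2 && cfg$batch_confounding > 0) {
        pr <- 0.5 + cfg$batch_confounding *
          ifelse(rep(c(TRUE, FALSE), c(cfg$n_case, cfg$n_control)), 1, -1)
        1L + rbinom(n, 1, clamp(pr, 0, 1))
      } else sample(cfg$n_batches, n, TRUE)),
      stringsAsFactors = FALSE)
    scores <- matrix(rnorm(n * cfg$n_latent_factors), n, cfg$n_latent_factors)
    list(sheet = sheet, scores = scores)
  })
  sheet <- smp$sheet
  n <- nrow(sheet)

  ## linear predictor in percentage points, scaled to logit at each baseline;
  ## for affected cytosines the scale is the exact secant at the stated case
  ## shift, so the realized case-control difference equals delta exactly
  ## (the derivative would attenuate effects at extreme baselines)
  s_i <- 1 / (100 * b * (1 - b))
  aff <- which(eff$delta != 0)
  if (length(aff)) {
    shifted <- clamp(b[aff] + eff$delta[aff] / 100, cfg$eps, 1 - cfg$eps)
    s_i[aff] <- (qlogis(shifted) - qlogis(b[aff])) / eff$delta[aff]
  }
  case <- as.numeric(sheet$group == "case")
  age_c <- sheet$age - mean(sheet$age)
  batch_idx <- as.integer(sub("^B", "", sheet$batch))
  pct <- outer(eff$delta, case) +
    outer(eff$gamma, age_c) +
    eff$batch_off[, batch_idx, drop = FALSE] +
    eff$loadings %*% t(smp$scores)

  outliers <- withStream(nseed, "outliers", {
    if (cfg$n_outlier_samples < 1) list(ids = character(), shift = 0)
    else {
      ids <- sample(sheet$sample_id, cfg$n_outlier_samples)
      ## provisional count draw (own stream) to measure the spread of
      ## observed sample means, so the planted shift is outlier_shift_sd
      ## standard deviations of what the detector actually sees
      mu0 <- clamp(plogis(qlogis(b) + s_i * pct), cfg$eps, 1 - cfg$eps)
      nc <- ncol(mu0)
      N0 <- matrix(rnbinom(G * nc, mu = cfg$coverage_mean,
                           size = cfg$coverage_dispersion), G, nc)
      p0 <- if (cfg$rho > 0)
        matrix(rbeta(G * nc, mu0 * (1 - cfg$rho) / cfg$rho,
                     (1 - mu0) * (1 - cfg$rho) / cfg$rho), G, nc)
      else mu0
      B0 <- matrix(rbinom(G * nc, N0, p0), G, nc) / ifelse(N0 == 0, NA, N0)
      sm <- colMeans(B0, na.rm = TRUE)
      shift <- cfg$outlier_shift_sd * max(sd(sm), 1e-4) * 100
      list(ids = ids, shift = shift)
    }
  })
  if (length(outliers$ids))
    pct[, match(outliers$ids, sheet$sample_id)] <-
      pct[, match(outliers$ids, sheet$sample_id)] + outliers$shift

  eta <- qlogis(b) + s_i * pct
  mu_raw <- plogis(eta)
  mu <- clamp(mu_raw, cfg$eps, 1 - cfg$eps)
  clamped <- mean(mu_raw < cfg$eps | mu_raw > 1 - cfg$eps)
  if (clamped > 0.01)
    warning(sprintf("%.1f%% of cells clamped at epsilon; check effect sizes vs baselines",
                    100 * clamped))

  drawCounts <- function(mu_mat, stream) {
    withStream(nseed, stream, {
      nc <- ncol(mu_mat)
      N <- matrix(rnbinom(G * nc, mu = cfg$coverage_mean,
                          size = cfg$coverage_dispersion), G, nc)
      p <- if (cfg$rho > 0) {
        a <- mu_mat * (1 - cfg$rho) / cfg$rho
        bb <- (1 - mu_mat) * (1 - cfg$rho) / cfg$rho
        matrix(rbeta(G * nc, a, bb), G, nc)
      } else mu_mat
      M <- matrix(rbinom(G * nc, N, p), G, nc)
      U <- N - M
      miss <- N == 0
      M[miss] <- NA_integer_; U[miss] <- NA_integer_
      list(M = M, U = U)
    })
  }
  cnt <- drawCounts(mu, "counts")
  M <- cnt$M; U <- cnt$U
  colnames(M) <- colnames(U) <- sheet$sample_id
  sheet$replicate_group <- NA_character_

  if (cfg$n_replicate_pairs > 0) {
    rep_of <- withStream(nseed, "replicates",
                         sample(sheet$sample_id, cfg$n_replicate_pairs))
    rc <- drawCounts(mu[, match(rep_of, sheet$sample_id), drop = FALSE],
                     "replicates")
    rep_ids <- paste0(rep_of, "_rep")
    colnames(rc$M) <- colnames(rc$U) <- rep_ids
    M <- cbind(M, rc$M); U <- cbind(U, rc$U)
    extra <- sheet[match(rep_of, sheet$sample_id), ]
    extra$sample_id <- rep_ids
    sheet$replicate_group[match(rep_of, sheet$sample_id)] <- rep_of
    extra$replicate_group <- rep_of
    sheet <- rbind(sheet, extra)
    rownames(sheet) <- NULL
  }

  counts <- MethylCountSet(M, U, lay$keys, sheet)
  annotation <- PanelAnnotation(lay$genes, lay$elements)
  ids <- cytosineKey(lay$keys$chrom, lay$keys$pos, lay$keys$strand,
                     lay$keys$context)
  truth <- list(
    cytosine = data.frame(key = ids, gene_id = lay$site_gene,
                          baseline = b, delta = eff$delta, gamma = eff$gamma,
                          stringsAsFactors = FALSE),
    batch_offsets = eff$batch_off,
    latent_loadings = eff$loadings,
    latent_scores = smp$scores,
    mu = mu,
    outlier_samples = outliers$ids,
    outlier_shift_pct = outliers$shift,
    clamped_fraction = clamped,
    seed = cfg$seed)
  list(counts = counts, annotation = annotation, truth = truth)
}

#' Simulate a null panel (no case or age effects)
#'
#' [simulatePanel()] with `frac_affected_genes = 0` and
#' `frac_age_cytosines = 0`; batch and latent structure are kept.
#'
#' @param cfg a [simConfig()] list.
#' @return as [simulatePanel()].
#' @export
simulateNull <- function(cfg = simConfig()) {
  cfg$frac_affected_genes <- 0
  cfg$frac_age_cytosines <- 0
  simulatePanel(cfg)
}

#' Write simulation outputs as pipeline input files
#'
#' @param sim result of [simulatePanel()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(counts = file.path(dir, "counts.tsv"),
         sheet = file.path(dir, "samples.csv"),
         genes = file.path(dir, "genes.tsv"),
         elements = file.path(dir, "elements.bed"),
         truth = file.path(dir, "truth.tsv"))
  writeCounts(sim$counts, p["counts"], seed = sim$truth$seed)
  writeSampleSheet(sim$counts, p["sheet"])
  writePanelGenes(sim$annotation, p["genes"])
  el <- panelElements(sim$annotation)
  gr <- unlist(el, use.names = FALSE)
  gr$name <- rep(names(el), lengths(el))
  writeBedIntervals(gr, p["elements"])
  writeTsv(sim$truth$cytosine, p["truth"], seed = sim$truth$seed)
  invisible(p)
}
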