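#' Cohort configuration for the synthetic-data generator
#'
#' Describes a simulated patient cohort: group sizes, per-subject cell
#' counts, the qPCR gene panel, group-level expression effects, subject-level
#' JAK1 on/off assignment, correlated transcript blocks, dropout and
#' artifact rates. Defaults emulate the study design the analysis assumes:
#' 15 subjects split 3/6/6 over groups `ND` (serum type I IFN not detected),
#' `low_ratio` (IFN-beta/alpha at most 1.3) and `high_ratio` (above 1.3),
#' with classical (CL) and non-classical (NC) monocytes captured per subject.
#'
#' @param n_per_group Named integer vector of subjects per group; names from
#'   `c("ND", "low_ratio", "high_ratio")`.
#' @param cells_per_subject Named integer vector of cells per lineage for
#'   each subject, names `c("CL", "NC")`.
#' @param cells_per_group Optional named list `group -> c(CL = n, NC = n)`
#'   of *total* cells per group and lineage, distributed as evenly as
#'   possible across the group's subjects (overrides `cells_per_subject`).
#' @param panel Character vector of panel genes (default [defaultPanel()]).
#' @param group_effects Named list `group -> list(dp = , dct = )` of per-gene
#'   expression-probability offsets and mean-Ct shifts (negative shift =
#'   higher expression); default [defaultGroupEffects()].
#' @param jak1_onoff_assignment Named numeric vector: probability that a
#'   subject of each group is a JAK1 non-expresser.
#' @param jak1_expresser_rates Per-lineage per-cell JAK1 detection rate in
#'   expresser subjects (defaults CL 0.83, NC 0.99).
#' @param correlation_blocks List of `list(genes = , rho = )` blocks; within
#'   a block, amplified Ct values share a per-cell latent factor tuned to the
#'   target Spearman correlation.
#' @param dropout_base Baseline per-gene probability a transcript is *not*
#'   detected in a cell.
#' @param failure_rate Probability a cell is globally degraded (elevated Ct
#'   across the panel).
#' @param well_artifact_rates Named numeric vector `c(empty=, doublet=,
#'   curve=)`: rates of artifact wells emitted in addition to the requested
#'   cells.
#' @param base_ct,ct_sd Mean and SD of amplified Ct values for an unshifted
#'   gene.
#' @param failure_ct_shift Cycles added to every amplified Ct of a degraded
#'   cell.
#' @param lod_ct Limit-of-detection cycle used downstream for the Et
#'   transform.
#' @param seed Integer seed; all generation is deterministic given the
#'   config.
#' @return A validated list of class `"CohortConfig"`.
#' @export
#' @examples
#' cfg <- cohortConfig(seed = 7)
#' cohort <- generateCohort(cfg)
#' table(cohort$group)
cohortConfig <- function(n_per_group = c(ND = 3L, low_ratio = 6L,
                                         high_ratio = 6L),
                         cells_per_subject = c(CL = 25L, NC = 25L),
                         cells_per_group = NULL,
                         panel = defaultPanel(),
                         group_effects = defaultGroupEffects(),
                         jak1_onoff_assignment = c(ND = 0.9, low_ratio = 0.15,
                                                   high_ratio = 0.9),
                         jak1_expresser_rates = c(CL = 0.83, NC = 0.99),
                         correlation_blocks = defaultCorrelationBlocks(),
                         dropout_base = 0.3,
                         failure_rate = 0.03,
                         well_artifact_rates = c(empty = 0.03, doublet = 0.02,
                                                 curve = 0.02),
                         base_ct = 22, ct_sd = 1.5,
                         failure_ct_shift = 12,
                         lod_ct = 28,
                         seed = 1L) {
  cfg <- list(n_per_group = n_per_group,
              cells_per_subject = cells_per_subject,
              cells_per_group = cells_per_group,
              panel = panel, group_effects = group_effects,
              jak1_onoff_assignment = jak1_onoff_assignment,
              jak1_expresser_rates = jak1_expresser_rates,
              correlation_blocks = correlation_blocks,
              dropout_base = dropout_base, failure_rate = failure_rate,
              well_artifact_rates = well_artifact_rates,
              base_ct = base_ct, ct_sd = ct_sd,
              failure_ct_shift = failure_ct_shift,
              lod_ct = lod_ct, seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a CohortConfig
#'
#' Checks the generator invariants: probabilities in `[0, 1]`, no duplicate
#' panel genes, non-negative cell counts, group labels drawn from the three
#' recognised groups.
#'
#' @param cfg A `"CohortConfig"` list.
#' @return `cfg`, invisibly; stops with a configuration error otherwise.
#' @export
validateCohortConfig <- function(cfg) {
  valid_groups <- c("ND", "low_ratio", "high_ratio")
  if (!all(names(cfg$n_per_group) %in% valid_groups))
    stop("configuration error: group labels must be among ",
         paste(valid_groups, collapse = ", "))
  if (any(cfg$n_per_group < 0))
    stop("configuration error: n_per_group must be >= 0")
  if (anyDuplicated(cfg$panel))
    stop("configuration error: duplicate gene names in panel")
  if (any(cfg$cells_per_subject < 0))
    stop("configuration error: cells_per_subject must be >= 0")
  probs <- c(cfg$jak1_onoff_assignment, cfg$dropout_base, cfg$failure_rate,
             cfg$well_artifact_rates, cfg$jak1_expresser_rates)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$lod_ct <= 0 || cfg$lod_ct > 40)
    stop("configuration error: lod_ct must lie in (0, 40]")
  for (bl in cfg$correlation_blocks) {
    if (!all(bl$genes %in% cfg$panel))
      stop("configuration error: correlation-block gene not in panel")
    if (bl$rho < 0 || bl$rho >= 1)
      stop("configuration error: block rho must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Default group-level expression effects
#'
#' Per-group per-gene offsets applied by the single-cell simulator:
#' `dp` shifts the expression probability, `dct` shifts the mean Ct of
#' amplified values (negative = more transcript). Defaults plant the
#' qualitative structure of the study: several transcripts (HLADRB1, TNFA,
#' PDL1, TGFB, CD11c, IL8, IFNAR1) enriched in the ND and high-ratio groups,
#' and the interferon-stimulated gene IFI27 depleted in those groups.
#'
#' @return Named list `group -> list(dp, dct)` of named numeric vectors.
#' @export
defaultGroupEffects <- function() {
  up <- c("HLADRB1", "TNFA", "PDL1", "TGFB", "CD11c", "IL8", "IFNAR1")
  dn <- c("IFI27")
  eff <- list(
    dp = c(stats::setNames(rep(0.2, length(up)), up),
           stats::setNames(rep(-0.25, length(dn)), dn)),
    dct = c(stats::setNames(rep(-1.5, length(up)), up),
            stats::setNames(rep(1.5, length(dn)), dn))
  )
  list(ND = eff, low_ratio = list(dp = numeric(), dct = numeric()),
       high_ratio = eff)
}

#' Default correlated transcript blocks
#'
#' One interferon-stimulated-gene block with a moderate target Spearman
#' correlation, realised through a shared per-cell latent factor.
#'
#' @return List of `list(genes, rho)` blocks.
#' @export
defaultCorrelationBlocks <- function() {
  list(list(genes = c("IFI27", "IFIT2", "ISG15", "OAS1", "MX2"), rho = 0.4))
}

#' Reporter-assay simulation parameters
#'
#' Parameters of the simulated WISH reporter assay used to emit serum Ct
#' records. Antibody blocking is modelled through efficiency fractions
#' (the laboratory antibody concentrations are metadata, not dose-response
#' inputs). Induction follows
#' `Ct = baseline - induction_slope * log2(1 + activity) + noise`, so with
#' slope 1 the fold change relative to an unstimulated healthy baseline is
#' linear in activity and activity units survive the delta-delta-Ct readout.
#'
#' @param induction_slope Delta-Ct per doubling of (1 + activity).
#' @param baseline_ct Ct of each reporter target at zero activity.
#' @param housekeeping_ct Ct of the housekeeping control.
#' @param ct_noise_sd Measurement noise SD, cycles.
#' @param anti_alpha_efficiency,anti_beta_efficiency Fraction of the blocked
#'   subtype's activity removed by the antibody, in `(0, 1]`.
#' @param healthy_panel_size Number of healthy reference donors.
#' @param pg_per_activity_unit Calibration: pg/mL per latent activity unit.
#' @param antibody_conc Named record of the antibody concentrations
#'   (metadata only).
#' @return A validated list of class `"AssayParams"`.
#' @export
assayParams <- function(induction_slope = 1,
                        baseline_ct = 27,
                        housekeeping_ct = 18,
                        ct_noise_sd = 0.15,
                        anti_alpha_efficiency = 0.95,
                        anti_beta_efficiency = 0.95,
                        healthy_panel_size = 12L,
                        pg_per_activity_unit = 1,
                        antibody_conc = c(anti_alpha_ug_ml = 19.6,
                                          anti_beta_ug_ml = 10.1)) {
  if (anti_alpha_efficiency <= 0 || anti_alpha_efficiency > 1 ||
      anti_beta_efficiency <= 0 || anti_beta_efficiency > 1)
    stop("configuration error: blocking efficiencies must lie in (0, 1]")
  if (ct_noise_sd < 0)
    stop("configuration error: ct_noise_sd must be >= 0")
  if (healthy_panel_size < 3)
    stop("configuration error: healthy panel needs >= 3 donors")
  structure(list(induction_slope = induction_slope,
                 baseline_ct = baseline_ct,
                 housekeeping_ct = housekeeping_ct,
                 ct_noise_sd = ct_noise_sd,
                 anti_alpha_efficiency = anti_alpha_efficiency,
                 anti_beta_efficiency = anti_beta_efficiency,
                 healthy_panel_size = as.integer(healthy_panel_size),
                 pg_per_activity_unit = pg_per_activity_unit,
                 antibody_conc = antibody_conc),
            class = "AssayParams")
}

## ---------------------------------------------------------------------------
## Cohort generation
## ---------------------------------------------------------------------------

#' Generate a synthetic cohort of subject profiles
#'
#' Draws one latent profile per subject: group, IFN-alpha and IFN-beta
#' activities (log-normal totals for detected groups, sub-detection totals
#' for ND), and a JAK1 expresser/non-expresser state. Activities respect
#' the group definitions: `high_ratio` subjects have beta/alpha > 1.3,
#' `low_ratio` subjects at most 1.3, and `ND` subjects a total activity
#' below the 1 pg/mL-equivalent detection level.
#'
#' @param config A [cohortConfig()] object.
#' @return `data.frame` with columns `subject_id`, `group`,
#'   `alpha_activity`, `beta_activity`, `jak1_state`.
#' @export
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 42))
#' head(cohort)
generateCohort <- function(config) {
  validateCohortConfig(config)
  withr::with_seed(config$seed, {
    rows <- lapply(names(config$n_per_group), function(g) {
      n <- config$n_per_group[[g]]
      if (n == 0L) return(NULL)
      total <- switch(g,
        ND = stats::runif(n, 0.05, 0.5),
        stats::rlnorm(n, meanlog = log(10), sdlog = 0.3))
      ratio <- switch(g,
        ND = stats::runif(n, 0.5, 2),
        low_ratio = stats::runif(n, 0.35, 1.05),
        high_ratio = stats::runif(n, 1.7, 3.5))
      alpha <- total / (1 + ratio)
      beta <- total - alpha
      nonexp <- stats::runif(n) < config$jak1_onoff_assignment[[g]]
      data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)),
                 group = g, alpha_activity = alpha, beta_activity = beta,
                 jak1_state = ifelse(nonexp, "non-expresser", "expresser"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(subject_id = character(), group = character(),
                        alpha_activity = numeric(), beta_activity = numeric(),
                        jak1_state = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

## ---------------------------------------------------------------------------
## Serum reporter assay simulation
## ---------------------------------------------------------------------------

.serumCt <- function(activity, params, n = 3L) {
  params$baseline_ct -
    params$induction_slope * log2(1 + pmax(activity, 0)) +
    stats::rnorm(n, 0, params$ct_noise_sd)
}

#' Simulate the reporter assay for one subject
#'
#' Emits Ct values for the three reporter targets plus housekeeping under
#' three conditions: untreated serum (activity alpha + beta), serum
#' pre-incubated with anti-IFN-alpha (residual
#' `alpha * (1 - eff_alpha) + beta`), and with anti-IFN-beta (residual
#' `alpha + beta * (1 - eff_beta)`). More activity means lower target Ct.
#' Uses the current RNG state; seed at the cohort level via
#' [simulateSerum()].
#'
#' @param subject One-row `data.frame` with `subject_id`, `alpha_activity`,
#'   `beta_activity`.
#' @param params An [assayParams()] object.
#' @return Long `data.frame`: `subject_id`, `condition` (`none`,
#'   `anti_alpha`, `anti_beta`), `gene`, `ct`.
#' @export
simulateSerumAssay <- function(subject, params) {
  stopifnot(nrow(subject) == 1L)
  if (subject$alpha_activity < 0 || subject$beta_activity < 0)
    stop("subject activities must be >= 0")
  sp <- serumPanel()
  a <- subject$alpha_activity
  b <- subject$beta_activity
  acts <- c(none = a + b,
            anti_alpha = a * (1 - params$anti_alpha_efficiency) + b,
            anti_beta = a + b * (1 - params$anti_beta_efficiency))
  rows <- lapply(names(acts), function(cond) {
    ct_t <- .serumCt(acts[[cond]], params, length(sp$targets))
    data.frame(subject_id = subject$subject_id, condition = cond,
               gene = c(sp$targets, sp$housekeeping),
               ct = c(ct_t, params$housekeeping_ct +
                        stats::rnorm(1, 0, params$ct_noise_sd)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate serum assays for a cohort, with a healthy reference panel
#'
#' Runs [simulateSerumAssay()] for each subject and appends a healthy-donor
#' reference panel (zero activity) of `params$healthy_panel_size` donors
#' under condition `healthy_ref`.
#'
#' @param cohort Output of [generateCohort()].
#' @param params An [assayParams()] object.
#' @param seed Integer seed (default: deterministic from nothing; pass one
#'   for reproducibility).
#' @return Long `data.frame` with columns `subject_id`, `condition`,
#'   `gene`, `ct`.
#' @export
simulateSerum <- function(cohort, params = assayParams(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    subj <- lapply(seq_len(nrow(cohort)), function(i)
      simulateSerumAssay(cohort[i, , drop = FALSE], params))
    sp <- serumPanel()
    healthy <- lapply(seq_len(params$healthy_panel_size), function(d) {
      ct_t <- .serumCt(0, params, length(sp$targets))
      data.frame(subject_id = sprintf("healthy_%02d", d),
                 condition = "healthy_ref",
                 gene = c(sp$targets, sp$housekeeping),
                 ct = c(ct_t, params$housekeeping_ct +
                          stats::rnorm(1, 0, params$ct_noise_sd)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(subj, healthy))
    rownames(out) <- NULL
    out
  })
}

## ---------------------------------------------------------------------------
## Single-cell simulation
## ---------------------------------------------------------------------------

.cellCountsFor <- function(config, group, lineage, n_subjects, idx) {
  if (!is.null(config$cells_per_group)) {
    tot <- config$cells_per_group[[group]][[lineage]]
    if (is.null(tot)) stop("configuration error: lineage '", lineage,
                           "' absent from cells_per_group for ", group)
    base <- tot %/% n_subjects
    extra <- tot %% n_subjects
    base + as.integer(idx <= extra)
  } else {
    if (!lineage %in% names(config$cells_per_subject))
      stop("configuration error: lineage '", lineage,
           "' absent from cells_per_subject")
    config$cells_per_subject[[lineage]]
  }
}

.geneParams <- function(config, group, lineage) {
  panel <- config$panel
  p <- stats::setNames(rep(1 - config$dropout_base, length(panel)), panel)
  mu <- stats::setNames(rep(config$base_ct, length(panel)), panel)
  eff <- config$group_effects[[group]]
  if (!is.null(eff)) {
    common <- intersect(names(eff$dp), panel)
    p[common] <- pmin(1, pmax(0, p[common] + eff$dp[common]))
    common <- intersect(names(eff$dct), panel)
    mu[common] <- mu[common] + eff$dct[common]
  }
  list(p = p, mu = mu)
}

## Correlated standard-normal draws: genes in a block share a per-cell
## factor with Pearson loading 2*sin(pi*rho/6), the exact bivariate-normal
## inverse of the target Spearman correlation.
.cellLatent <- function(config, n_cells) {
  panel <- config$panel
  z <- matrix(stats::rnorm(length(panel) * n_cells), nrow = length(panel),
              dimnames = list(panel, NULL))
  for (bl in config$correlation_blocks) {
    r <- 2 * sin(pi * bl$rho / 6)
    f <- stats::rnorm(n_cells)
    genes <- intersect(bl$genes, panel)
    z[genes, ] <- sqrt(r) * matrix(f, nrow = length(genes), ncol = n_cells,
                                   byrow = TRUE) +
      sqrt(1 - r) * z[genes, , drop = FALSE]
  }
  z
}

#' Simulate single-cell qPCR wells for one subject
#'
#' Per lineage, emits the requested number of real cells plus artifact
#' wells (empty, doublet, curve-fail) at the configured rates. Gene-wise
#' expression is Bernoulli with group-dependent probability; amplified Ct
#' values are Gaussian around group-shifted means with correlated-block
#' structure; degraded ("failure") cells have all amplified Ct values
#' elevated by `failure_ct_shift`. JAK1 is never amplified in non-expresser
#' subjects, and is detected at the per-lineage expresser rates otherwise.
#' Uses the current RNG state; seed at the cohort level via
#' [simulateCells()].
#'
#' @param subject One-row `data.frame` from [generateCohort()].
#' @param config A [cohortConfig()] object.
#' @param subject_index,n_in_group Position of the subject within its group
#'   and the group size (used only to distribute `cells_per_group` totals).
#' @return A [CtWellSet-class] with this subject's wells.
#' @export
simulateSingleCells <- function(subject, config, subject_index = 1L,
                                n_in_group = 1L) {
  validateCohortConfig(config)
  stopifnot(nrow(subject) == 1L)
  panel <- config$panel
  lineages <- if (!is.null(config$cells_per_group))
    names(config$cells_per_group[[subject$group]])
  else names(config$cells_per_subject)
  all_ct <- list(); all_wd <- list()
  for (lin in lineages) {
    n_real <- .cellCountsFor(config, subject$group, lin, n_in_group,
                             subject_index)
    rates <- config$well_artifact_rates
    n_empty <- stats::rbinom(1, n_real, rates[["empty"]])
    n_doub <- stats::rbinom(1, n_real, rates[["doublet"]])
    n_curve <- stats::rbinom(1, n_real, rates[["curve"]])
    n_tot <- n_real + n_empty + n_doub + n_curve
    if (n_tot == 0L) next
    gp <- .geneParams(config, subject$group, lin)
    p <- gp$p
    p["JAK1"] <- if (subject$jak1_state == "non-expresser") 0
                 else config$jak1_expresser_rates[[lin]]
    ## simulate the non-empty wells (real + doublet + curve) in one batch
    n_sim <- n_real + n_doub + n_curve
    ct <- matrix(NA_real_, nrow = length(panel), ncol = n_tot,
                 dimnames = list(panel, NULL))
    if (n_sim > 0) {
      z <- .cellLatent(config, n_sim)
      expressed <- matrix(stats::runif(length(panel) * n_sim),
                          nrow = length(panel)) < p
      vals <- gp$mu + config$ct_sd * z
      failed <- stats::runif(n_sim) < config$failure_rate
      vals[, failed] <- vals[, failed, drop = FALSE] + config$failure_ct_shift
      ## doublets carry roughly twice the template: one cycle earlier
      doub_cols <- seq_len(n_doub) + n_real
      if (n_doub > 0) vals[, doub_cols] <- vals[, doub_cols, drop = FALSE] - 1
      vals <- pmin(pmax(vals, 5), 40)
      vals[!expressed] <- NA_real_
      ct[, seq_len(n_sim)] <- vals
    } else {
      failed <- logical(0)
    }
    flag_doublet <- c(rep(FALSE, n_real), rep(TRUE, n_doub),
                      rep(FALSE, n_curve), rep(FALSE, n_empty))
    flag_curve <- c(rep(FALSE, n_real + n_doub), rep(TRUE, n_curve),
                    rep(FALSE, n_empty))
    flag_empty <- c(rep(FALSE, n_sim), rep(TRUE, n_empty))
    wd <- data.frame(
      well_id = sprintf("%s_%s_w%03d", subject$subject_id, lin,
                        seq_len(n_tot)),
      subject_id = subject$subject_id, lineage = lin,
      run_id = paste(subject$subject_id, lin, sep = ":"),
      flag_empty = flag_empty, flag_doublet = flag_doublet,
      flag_curve = flag_curve,
      is_failure = c(failed, rep(FALSE, n_empty)),
      stringsAsFactors = FALSE)
    all_ct[[length(all_ct) + 1L]] <- ct
    all_wd[[length(all_wd) + 1L]] <- wd
  }
  if (!length(all_ct)) {
    ct <- matrix(NA_real_, nrow = length(panel), ncol = 0,
                 dimnames = list(panel, NULL))
    wd <- data.frame(well_id = character(), subject_id = character(),
                     lineage = character(), run_id = character(),
                     flag_empty = logical(), flag_doublet = logical(),
                     flag_curve = logical(), is_failure = logical())
    return(CtWellSet(ct, wd))
  }
  CtWellSet(do.call(cbind, all_ct), do.call(rbind, all_wd))
}

#' Simulate single-cell wells for a whole cohort
#'
#' @param cohort Output of [generateCohort()].
#' @param config A [cohortConfig()] object (its `seed`, offset by one, seeds
#'   the cell-level RNG independently of cohort generation).
#' @return A combined [CtWellSet-class].
#' @export
#' @examples
#' cfg <- cohortConfig(cells_per_subject = c(CL = 5, NC = 5), seed = 3)
#' cells <- simulateCells(generateCohort(cfg), cfg)
#' cells
simulateCells <- function(cohort, config) {
  validateCohortConfig(config)
  withr::with_seed(config$seed + 1L, {
    parts <- lapply(seq_len(nrow(cohort)), function(i) {
      grp <- cohort$group[i]
      in_grp <- which(cohort$group == grp)
      simulateSingleCells(cohort[i, , drop = FALSE], config,
                          subject_index = match(i, in_grp),
                          n_in_group = length(in_grp))
    })
  })
  ct <- do.call(cbind, lapply(parts, assay, "Ct"))
  wd <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(colData(p))))
  rownames(wd) <- NULL
  CtWellSet(ct, wd)
}

## ---------------------------------------------------------------------------
## Fixture writers / readers (long-format CSV)
## ---------------------------------------------------------------------------

#' Write a synthetic cohort fixture to disk
#'
#' Writes three long-format CSV files: `cohort.csv` (latent subject truth),
#' `serum.csv` (reporter-assay records incl. healthy panel) and
#' `single_cells.csv` (well flags and per-gene Ct, empty field = no
#' amplification). Files round-trip losslessly through [readSerumCSV()] and
#' [readSingleCellCSV()].
#'
#' @param cohort Output of [generateCohort()].
#' @param serum Output of [simulateSerum()].
#' @param cells A [CtWellSet-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeFixture <- function(cohort, serum, cells, dir) {
  if (ncol(cells) == 0L && nrow(serum) == 0L && nrow(cohort) == 0L)
    stop("records are empty; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             serum = file.path(dir, "serum.csv"),
             cells = file.path(dir, "single_cells.csv"))
  utils::write.csv(cohort, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(serum, paths[["serum"]], row.names = FALSE)
  cd <- as.data.frame(colData(cells))
  ct <- assay(cells, "Ct")
  long <- data.frame(
    well_id = rep(cd$well_id, each = nrow(ct)),
    subject_id = rep(cd$subject_id, each = nrow(ct)),
    lineage = rep(cd$lineage, each = nrow(ct)),
    flag_empty = rep(cd$flag_empty, each = nrow(ct)),
    flag_doublet = rep(cd$flag_doublet, each = nrow(ct)),
    flag_curve = rep(cd$flag_curve, each = nrow(ct)),
    gene = rep(rownames(ct), times = ncol(ct)),
    ct = as.vector(ct), stringsAsFactors = FALSE)
  utils::write.csv(long, paths[["cells"]], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read a serum reporter-assay CSV
#'
#' @param path CSV with columns `subject_id`, `condition`, `gene`, `ct`.
#' @return Long `data.frame` as produced by [simulateSerum()].
#' @export
readSerumCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "condition", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("serum CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a single-cell long-format CSV into a CtWellSet
#'
#' @param path CSV with columns `well_id`, `subject_id`, `lineage`,
#'   `flag_empty`, `flag_doublet`, `flag_curve`, `gene`, `ct` (empty field =
#'   no amplification). Gene order of the first well defines the panel.
#' @return A [CtWellSet-class].
#' @export
readSingleCellCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = c(ct = "numeric"))
  panel <- unique(df$gene)
  wells <- unique(df$well_id)
  ct <- matrix(NA_real_, nrow = length(panel), ncol = length(wells),
               dimnames = list(panel, wells))
  ct[cbind(match(df$gene, panel), match(df$well_id, wells))] <- df$ct
  first <- df[!duplicated(df$well_id),
              c("well_id", "subject_id", "lineage",
                "flag_empty", "flag_doublet", "flag_curve")]
  first$run_id <- paste(first$subject_id, first$lineage, sep = ":")
  rownames(first) <- NULL
  CtWellSet(ct, first)
}
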