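#' Simulation configuration for a synthetic cohort
#'
#' Defaults describe a toy cohort on the [toy_genome()] build: whole-arm
#' single-copy gains/losses at moderate per-arm rates, occasional focal
#' gains and high-level amplifications, and Gaussian segment noise on
#' the ploidy-normalized log2 scale. Breakpoints live on a 10-kb
#' lattice (`breakpoint_unit`), which is the coordinate granularity of
#' the simulated data and the resolution at which exhaustive per-base
#' oracles operate.
#'
#' @param seed integer seed.
#' @param n_samples cohort size.
#' @param genome a genome build, default [toy_genome()].
#' @param arm_gain_prob,arm_loss_prob per-arm event probabilities.
#' @param focal_rate mean number of focal gains per sample (Poisson).
#' @param focal_len_range focal event length range in bp.
#' @param amp_rate probability a sample carries one amplification.
#' @param amp_len_range amplification length range in bp.
#' @param gain_level,loss_level,amp_level planted log2 levels (single
#'   copy gain/loss and high-level amplification).
#' @param noise_sd per-segment Gaussian noise sd (log2 scale).
#' @param breakpoint_unit breakpoint lattice in bp.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_samples = 200L, genome = toy_genome(),
                       arm_gain_prob = 0.15, arm_loss_prob = 0.10,
                       focal_rate = 1, focal_len_range = c(2e6, 20e6),
                       amp_rate = 0.05, amp_len_range = c(0.5e6, 3e6),
                       gain_level = 0.3, loss_level = -0.35,
                       amp_level = 1.2, noise_sd = 0.1,
                       breakpoint_unit = 1e4) {
  stopifnot(n_samples >= 1, arm_gain_prob >= 0, arm_gain_prob <= 1,
            arm_loss_prob >= 0, arm_loss_prob <= 1,
            loss_level < 0, gain_level > 0, amp_level > gain_level)
  structure(as.list(environment()), class = "sim_config")
}

# snap a coordinate to the breakpoint lattice
snap <- function(x, unit) round(x / unit) * unit

#' Simulate segmented copy-number profiles with planted events
#'
#' Per sample and chromosome arm, draws an arm-level gain (probability
#' `arm_gain_prob`) or loss (`arm_loss_prob`), overlays Poisson-many
#' focal gains and (with probability `amp_rate`) one amplification at
#' random positions, and emits per-arm segments at level + Gaussian
#' noise. The centromere interior carries no segments (as with real
#' profiling platforms). Focal events longer than their arm are
#' resampled.
#'
#' @param config from [sim_config()].
#' @return list with `segments` (long data.frame `sample`, `chrom`,
#'   `start`, `end`, `cn`) and `truth` (data.frame `sample`, `kind`,
#'   `chrom`, `arm`, `start`, `end`, `level`).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  arms <- arm_intervals(config$genome)
  unit <- config$breakpoint_unit
  seg_rows <- list(); truth_rows <- list()
  for (i in seq_len(config$n_samples)) {
    smp <- sprintf("S%04d", i)
    # arm-level events
    u <- stats::runif(nrow(arms))
    arm_level <- ifelse(u < config$arm_gain_prob, config$gain_level,
                        ifelse(u < config$arm_gain_prob + config$arm_loss_prob,
                               config$loss_level, 0))
    # focal gains
    n_focal <- stats::rpois(1, config$focal_rate)
    focal <- list()
    draw_focal <- function(level, kind, len_range) {
      repeat {
        a <- sample.int(nrow(arms), 1)
        len <- snap(stats::runif(1, len_range[1], len_range[2]), unit)
        arm_len <- arms$end[a] - arms$start[a]
        if (len >= unit && len <= arm_len) break
        # length incompatible with the arm: redraw
      }
      start <- snap(stats::runif(1, arms$start[a], arms$end[a] - len), unit)
      start <- min(max(start, arms$start[a]), arms$end[a] - len)
      list(arm = a, start = start, end = start + len, level = level,
           kind = kind)
    }
    if (n_focal > 0)
      focal <- lapply(seq_len(n_focal), function(j)
        draw_focal(config$gain_level, "focal_gain", config$focal_len_range))
    if (stats::runif(1) < config$amp_rate)
      focal <- c(focal, list(draw_focal(config$amp_level, "amplification",
                                        config$amp_len_range)))
    # record truth
    for (a in which(arm_level != 0)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = smp,
        kind = if (arm_level[a] > 0) "arm_gain" else "arm_loss",
        chrom = arms$chrom[a], arm = arms$arm[a],
        start = arms$start[a], end = arms$end[a], level = arm_level[a],
        stringsAsFactors = FALSE)
    }
    for (f in focal) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = smp, kind = f$kind, chrom = arms$chrom[f$arm],
        arm = arms$arm[f$arm], start = f$start, end = f$end,
        level = f$level, stringsAsFactors = FALSE)
    }
    # emit segments arm by arm: focal events overwrite the arm level
    for (a in seq_len(nrow(arms))) {
      fa <- Filter(function(f) f$arm == a, focal)
      bp <- sort(unique(c(arms$start[a], arms$end[a],
                          unlist(lapply(fa, function(f) c(f$start, f$end))))))
      st <- bp[-length(bp)]; en <- bp[-1L]
      lev <- rep(arm_level[a], length(st))
      for (f in fa) {
        inside <- st >= f$start & en <= f$end
        lev[inside] <- pmax(lev[inside], f$level)
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        sample = smp, chrom = arms$chrom[a], start = st, end = en,
        cn = lev + stats::rnorm(length(st), 0, config$noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_rows)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(sample = character(), kind = character(),
                           chrom = character(), arm = character(),
                           start = numeric(), end = numeric(),
                           level = numeric())
  list(segments = segments, truth = truth)
}

#' Planted per-gene status implied by the genome truth ledger
#'
#' Derives, for each (sample, gene), the status the simulator planted:
#' `amplification` if an amplification event overlaps the gene,
#' otherwise `focal_gain` for a focal-gain overlap, `arm_gain` /
#' `loss` for an arm-level event on the gene's arm, else `neutral`.
#'
#' @param truth truth ledger from [simulate_genomes()].
#' @param genes gene bin table from [gene_bins()].
#' @param samples character vector of all sample ids.
#' @return character matrix samples x genes.
#' @export
truth_gene_status <- function(truth, genes, samples) {
  st <- matrix("neutral", length(samples), nrow(genes),
               dimnames = list(samples, genes$bin_id))
  rank <- c(neutral = 0, loss = 1, arm_gain = 2, focal_gain = 3,
            amplification = 4)
  for (k in seq_len(nrow(truth))) {
    ev <- truth[k, ]
    hit <- genes$chrom == ev$chrom & genes$start < ev$end &
           genes$end > ev$start
    if (!any(hit)) next
    lab <- switch(ev$kind, arm_gain = "arm_gain", arm_loss = "loss",
                  focal_gain = "focal_gain", amplification = "amplification")
    cur <- st[ev$sample, hit]
    st[ev$sample, hit] <- ifelse(rank[lab] > rank[cur], lab, cur)
  }
  st
}

#' Simulate a status matrix directly
#'
#' Draws independent per-gene five-way statuses; a direct route to
#' group-structured data when segment-level detail is not needed.
#'
#' @param n_samples number of samples.
#' @param genes gene names.
#' @param probs named probabilities over
#'   `c("loss","neutral","arm_gain","focal_gain","amplification")`.
#' @param seed integer seed.
#' @return character matrix samples x genes.
#' @export
simulate_status_matrix <- function(n_samples, genes,
                                   probs = c(loss = 0.1, neutral = 0.6,
                                             arm_gain = 0.15,
                                             focal_gain = 0.1,
                                             amplification = 0.05),
                                   seed = 1L) {
  set.seed(seed)
  lev <- names(probs)
  m <- matrix(sample(lev, n_samples * length(genes), replace = TRUE,
                     prob = probs),
              n_samples, length(genes),
              dimnames = list(sprintf("S%04d", seq_len(n_samples)), genes))
  m
}

# shared machinery: matrix = baseline + planted status shift + noise
simulate_status_effect_matrix <- function(status, effects, baseline, sd,
                                          seed, kind) {
  set.seed(seed)
  out <- matrix(stats::rnorm(length(status), baseline, sd),
                nrow(status), ncol(status), dimnames = dimnames(status))
  truth <- list()
  for (g in names(effects)) {
    if (!g %in% colnames(status)) next
    shift <- effects[[g]]
    for (stt in names(shift)) {
      rows <- !is.na(status[, g]) & status[, g] == stt
      out[rows, g] <- out[rows, g] + shift[[stt]]
      truth[[length(truth) + 1L]] <- data.frame(
        kind = kind, unit = g, status = stt, parameter = shift[[stt]],
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = out,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(kind = character(), unit = character(),
                               status = character(), parameter = numeric()))
}

#' Simulate dependency scores with planted status-dependent shifts
#'
#' Scores are baseline + shift(status) + Gaussian noise; shifts are
#' negative for genes the cohort is more dependent on when gained.
#'
#' @param status character status matrix samples x genes.
#' @param effects named list: gene -> named numeric vector of mean
#'   shifts per status (e.g. `list(MYC = c(focal_gain = -0.28))`).
#' @param baseline mean score for unaffected entries, default 0.
#' @param sd noise sd, default 0.3.
#' @param seed integer seed.
#' @return list with `dep` (matrix) and `truth` (planted-effect ledger).
#' @export
simulate_dependency <- function(status, effects = list(), baseline = 0,
                                sd = 0.3, seed = 1L) {
  r <- simulate_status_effect_matrix(status, effects, baseline, sd, seed,
                                     "dependency_shift")
  list(dep = r$matrix, truth = r$truth)
}

#' Simulate expression with planted upregulation in gained samples
#'
#' @inheritParams simulate_dependency
#' @param baseline mean log-expression, default 5.
#' @param sd noise sd, default 1.
#' @return list with `expression` and `truth`.
#' @export
simulate_expression <- function(status, effects = list(), baseline = 5,
                                sd = 1, seed = 1L) {
  r <- simulate_status_effect_matrix(status, effects, baseline, sd, seed,
                                     "expression_shift")
  list(expression = r$matrix, truth = r$truth)
}

#' Simulate drug-response AUC matrices with planted target-gain effects
#'
#' AUC = baseline + delta * [line has low-amplitude gain of the target]
#' + Gaussian noise (higher AUC = more resistant). Compounds in the
#' annotation with `delta_auc = 0` act as nulls.
#'
#' @param status character status matrix samples x genes.
#' @param annotation data.frame `compound`, `target`, `delta_auc`, and
#'   optional `screen`.
#' @param baseline mean AUC, default 0.5.
#' @param sd noise sd, default 0.15.
#' @param seed integer seed.
#' @return list with `auc` (lines x compounds), `truth`.
#' @export
simulate_drug_response <- function(status, annotation, baseline = 0.5,
                                   sd = 0.15, seed = 1L) {
  set.seed(seed)
  lines <- rownames(status)
  auc <- matrix(stats::rnorm(length(lines) * nrow(annotation), baseline, sd),
                length(lines), nrow(annotation),
                dimnames = list(lines, annotation$compound))
  for (i in seq_len(nrow(annotation))) {
    tg <- annotation$target[i]
    if (!tg %in% colnames(status) || annotation$delta_auc[i] == 0) next
    gained <- !is.na(status[, tg]) &
      status[, tg] %in% c("arm_gain", "focal_gain")
    auc[gained, i] <- auc[gained, i] + annotation$delta_auc[i]
  }
  truth <- annotation[annotation$delta_auc != 0, , drop = FALSE]
  truth <- data.frame(kind = "drug_effect", unit = truth$compound,
                      target = truth$target, parameter = truth$delta_auc,
                      stringsAsFactors = FALSE)
  list(auc = auc, truth = truth)
}

#' Simulate binary mutations with planted gain co-occurrence
#'
#' Per gene, mutations are Bernoulli with rate `base_rate` in lines
#' without low-amplitude gain; in gained lines the odds are multiplied
#' by the planted odds ratio.
#'
#' @param status character status matrix samples x genes.
#' @param odds_ratios named numeric vector gene -> planted OR (genes not
#'   listed get OR 1).
#' @param base_rate mutation rate in non-gained lines, default 0.15.
#' @param seed integer seed.
#' @return list with `mutations` (0/1 matrix over the status genes) and
#'   `truth`.
#' @export
simulate_mutations <- function(status, odds_ratios = numeric(),
                               base_rate = 0.15, seed = 1L) {
  set.seed(seed)
  genes <- colnames(status)
  mut <- matrix(0L, nrow(status), length(genes),
                dimnames = list(rownames(status), genes))
  odds0 <- base_rate / (1 - base_rate)
  for (g in genes) {
    or <- if (g %in% names(odds_ratios)) odds_ratios[[g]] else 1
    gained <- !is.na(status[, g]) & status[, g] %in% c("arm_gain", "focal_gain")
    p1 <- (odds0 * or) / (1 + odds0 * or)
    p <- ifelse(gained, p1, base_rate)
    mut[, g] <- stats::rbinom(nrow(status), 1, p)
  }
  truth <- data.frame(kind = rep("mutation_cooccurrence", length(odds_ratios)),
                      unit = if (length(odds_ratios)) names(odds_ratios)
                             else character(),
                      parameter = as.numeric(odds_ratios),
                      stringsAsFactors = FALSE)
  list(mutations = mut, truth = truth)
}

#' Simulate survival times with planted per-bin hazard ratios
#'
#' Exponential event times with per-sample hazard `base_hazard *
#' prod(HR^indicator)` and independent exponential censoring calibrated
#' to an approximate overall event rate.
#'
#' @param indicators 0/1 matrix samples x bins (e.g. gain indicators).
#' @param hazard_ratios named numeric vector bin -> planted HR.
#' @param base_hazard baseline hazard per day, default 1/1000.
#' @param event_rate target overall event fraction, default 0.4.
#' @param seed integer seed.
#' @return list with `surv` (data.frame `sample`, `time`, `event`) and
#'   `truth`.
#' @export
simulate_survival <- function(indicators, hazard_ratios = numeric(),
                              base_hazard = 1e-3, event_rate = 0.4,
                              seed = 1L) {
  set.seed(seed)
  n <- nrow(indicators)
  loghr <- rep(0, n)
  for (b in names(hazard_ratios)) {
    if (!b %in% colnames(indicators)) stop("bin ", b, " absent from indicators")
    loghr <- loghr + log(hazard_ratios[[b]]) * indicators[, b]
  }
  haz <- base_hazard * exp(loghr)
  t_event <- stats::rexp(n, haz)
  cens_rate <- base_hazard * (1 - event_rate) / event_rate
  t_cens <- stats::rexp(n, cens_rate)
  surv <- data.frame(sample = rownames(indicators),
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  truth <- data.frame(kind = rep("survival_hr", length(hazard_ratios)),
                      unit = if (length(hazard_ratios)) names(hazard_ratios)
                             else character(),
                      parameter = as.numeric(hazard_ratios),
                      stringsAsFactors = FALSE)
  list(surv = surv, truth = truth)
}
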