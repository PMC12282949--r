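#' Assemble the binary feature matrix for drug-response modelling
#'
#' Combines mutation indicators, per-bin copy-number state indicators
#' (separate gain / loss / amplification columns per bin) and one-hot
#' cancer type / subtype indicators over the shared cell lines. Constant
#' columns are dropped with a message.
#'
#' @param mutations binary matrix cell lines x genes; columns become
#'   `mut_<gene>`.
#' @param states character matrix cell lines x bins from [call_states()];
#'   yields `gain_<bin>` and `loss_<bin>` columns.
#' @param amp optional logical matrix cell lines x bins; yields
#'   `amp_<bin>` columns.
#' @param metadata data.frame with `sample`, `type`, `subtype`; yields
#'   `type_<t>` / `subtype_<s>` columns.
#' @return list with `X` (numeric 0/1 matrix, rows = shared lines) and
#'   `kind` (named character vector: mutation / bin_gain / bin_loss /
#'   bin_amp / type / subtype).
#' @export
build_feature_matrix <- function(mutations, states, amp = NULL, metadata) {
  lines <- Reduce(intersect, c(list(rownames(mutations), rownames(states),
                                    metadata$sample),
                               if (!is.null(amp)) list(rownames(amp))))
  if (!length(lines)) stop("no shared cell lines across inputs")
  lines <- sort(lines)
  blocks <- list(); kinds <- list()
  m <- mutations[lines, , drop = FALSE]
  colnames(m) <- paste0("mut_", colnames(m))
  blocks$mut <- m
  kinds$mut <- rep("mutation", ncol(m))
  st <- states[lines, , drop = FALSE]
  g <- (st == "gain") * 1; g[is.na(st)] <- 0
  l <- (st == "loss") * 1; l[is.na(st)] <- 0
  colnames(g) <- paste0("gain_", colnames(st))
  colnames(l) <- paste0("loss_", colnames(st))
  blocks$gain <- g; kinds$gain <- rep("bin_gain", ncol(g))
  blocks$loss <- l; kinds$loss <- rep("bin_loss", ncol(l))
  if (!is.null(amp)) {
    a <- (amp[lines, , drop = FALSE] %in% TRUE) * 1
    a <- matrix(a, nrow = length(lines),
                dimnames = list(lines, paste0("amp_", colnames(amp))))
    blocks$amp <- a; kinds$amp <- rep("bin_amp", ncol(a))
  }
  md <- metadata[match(lines, metadata$sample), , drop = FALSE]
  for (fld in c("type", "subtype")) {
    if (is.null(md[[fld]])) next
    lev <- sort(unique(md[[fld]]))
    oh <- sapply(lev, function(x) (md[[fld]] == x) * 1)
    oh <- matrix(oh, nrow = length(lines),
                 dimnames = list(lines, paste0(fld, "_", lev)))
    blocks[[fld]] <- oh
    kinds[[fld]] <- rep(fld, ncol(oh))
  }
  X <- do.call(cbind, blocks)
  kind <- stats::setNames(unlist(kinds), colnames(X))
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  if (any(!keep))
    message("dropped ", sum(!keep), " constant feature column(s)")
  list(X = X[, keep, drop = FALSE], kind = kind[keep])
}

#' Elastic-net configuration
#'
#' @param alpha mixing-parameter grid; the alpha with the lowest CV error
#'   is used. Default `c(0.1, 0.5, 0.9)`.
#' @param lambda_rule `"one_se"` (largest lambda within one SE of the CV
#'   minimum, default: keeps pure-noise responses from accumulating
#'   spurious features) or `"cv_min"`.
#' @param folds number of CV folds, default 5.
#' @param replicates number of replicate runs (differing only in fold
#'   assignment), default 3.
#' @return list of class `"enet_config"`.
#' @export
enet_config <- function(alpha = c(0.1, 0.5, 0.9),
                        lambda_rule = c("one_se", "cv_min"),
                        folds = 5L, replicates = 3L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(folds >= 2L, replicates >= 1L, all(alpha >= 0 & alpha <= 1))
  structure(list(alpha = alpha, lambda_rule = lambda_rule,
                 folds = folds, replicates = replicates),
            class = "enet_config")
}

#' One elastic-net feature-selection replicate
#'
#' Cross-validated glmnet fit over the lambda path for each alpha in the
#' grid; the (alpha, lambda) pair with the lowest CV error wins and the
#' features with nonzero coefficients at that point are returned. Binary
#' predictors are left unstandardized so coefficients stay interpretable
#' as per-indicator AUC shifts; the response is centred.
#'
#' @param X numeric feature matrix (rows = cell lines).
#' @param y numeric response (AUC) per row of `X`.
#' @param config from [enet_config()].
#' @param seed integer seed controlling fold assignment.
#' @param standardize standardize predictors (default FALSE).
#' @return data.frame `feature`, `coef`, `sign`; zero rows when the
#'   response is degenerate (with a warning).
#' @export
elastic_net_select <- function(X, y, config = enet_config(), seed = 1L,
                               standardize = FALSE) {
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(X) <= config$folds) stop("need more observations than folds")
  if (stats::sd(y) == 0) {
    warning("constant response; no features selected")
    return(data.frame(feature = character(), coef = numeric(),
                      sign = integer()))
  }
  y <- y - mean(y)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(config$folds), nrow(X)))
  fits <- lapply(config$alpha, function(a)
    glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                      standardize = standardize))
  cvm_min <- vapply(fits, function(f) min(f$cvm), 0)
  best <- fits[[which.min(cvm_min)]]
  s <- if (config$lambda_rule == "cv_min") best$lambda.min else best$lambda.1se
  cf <- as.matrix(stats::coef(best, s = s))[-1, 1]   # drop intercept
  nz <- cf[cf != 0]
  data.frame(feature = names(nz), coef = unname(nz),
             sign = as.integer(sign(nz)), stringsAsFactors = FALSE)
}

#' Intersect selected features across replicates
#'
#' Keeps only features selected in every replicate; a feature whose
#' coefficient sign flips across replicates is dropped with a warning.
#'
#' @param sets list of data.frames from [elastic_net_select()].
#' @return data.frame `feature`, `sign`, `present_in_replicates`,
#'   `mean_coef`.
#' @export
intersect_replicates <- function(sets) {
  stopifnot(length(sets) >= 1L)
  common <- Reduce(intersect, lapply(sets, `[[`, "feature"))
  if (!length(common))
    return(data.frame(feature = character(), sign = integer(),
                      present_in_replicates = integer(),
                      mean_coef = numeric()))
  signs <- sapply(sets, function(s) s$sign[match(common, s$feature)])
  signs <- matrix(signs, nrow = length(common))
  consistent <- apply(signs, 1, function(v) length(unique(v)) == 1L)
  if (any(!consistent))
    warning("dropped ", sum(!consistent),
            " feature(s) with inconsistent coefficient signs")
  common <- common[consistent]
  if (!length(common))
    return(data.frame(feature = character(), sign = integer(),
                      present_in_replicates = integer(),
                      mean_coef = numeric()))
  coefs <- sapply(sets, function(s) s$coef[match(common, s$feature)])
  coefs <- matrix(coefs, nrow = length(common))
  data.frame(feature = common, sign = signs[consistent, 1],
             present_in_replicates = length(sets),
             mean_coef = rowMeans(coefs), stringsAsFactors = FALSE)
}

#' Triplicate elastic-net selection for one compound
#'
#' Runs [elastic_net_select()] once per replicate (replicates differ only
#' in the CV fold assignment seed) and intersects the selected sets.
#' Type/subtype covariates stay in the model but are excluded from the
#' reported feature list.
#'
#' @param X,y,config as in [elastic_net_select()].
#' @param seeds integer vector, one per replicate (default `seed_base +
#'   0:(replicates-1)`).
#' @param seed_base base seed, default 1.
#' @param kind optional named kind vector from [build_feature_matrix()];
#'   used to drop type/subtype rows from the report.
#' @return data.frame of stable features as in [intersect_replicates()].
#' @export
run_elastic_net <- function(X, y, config = enet_config(), seeds = NULL,
                            seed_base = 1L, kind = NULL) {
  if (is.null(seeds)) seeds <- seed_base + seq_len(config$replicates) - 1L
  sets <- lapply(seeds, function(s) elastic_net_select(X, y, config, seed = s))
  stable <- intersect_replicates(sets)
  if (!is.null(kind)) {
    drop <- kind[stable$feature] %in% c("type", "subtype")
    stable <- stable[!drop, , drop = FALSE]
  }
  stable
}

#' Per-feature ANOVA conditional on cancer type and subtype
#'
#' Linear-model ANOVA p-value for one binary feature after cancer type
#' and subtype: `lm(y ~ type + subtype + feature)`, F-test on the
#' feature term. Features collinear with the covariates are untestable.
#'
#' @param y numeric response.
#' @param type,subtype factors (or vectors) per observation.
#' @param feature binary vector per observation.
#' @return list `p` (numeric or NA) and `untestable` flag.
#' @export
feature_anova <- function(y, type, subtype, feature) {
  d <- data.frame(y = y, type = factor(type), subtype = factor(subtype),
                  feature = feature)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$feature)) < 2L)
    return(list(p = NA_real_, untestable = TRUE))
  fit <- stats::lm(y ~ type + subtype + feature, data = d)
  if (is.na(stats::coef(fit)["feature"]))
    return(list(p = NA_real_, untestable = TRUE))   # collinear with covariates
  an <- stats::anova(fit)
  list(p = an["feature", "Pr(>F)"], untestable = FALSE)
}

#' ANOVA p/q-values for a set of selected (compound, feature) pairs
#'
#' @param pairs data.frame with `compound`, `feature`.
#' @param auc numeric matrix cell lines x compounds.
#' @param X feature matrix (same rows as `auc`).
#' @param metadata data.frame with `sample`, `type`, `subtype`.
#' @return `pairs` with `anova_p`, `anova_q`, `untestable` columns.
#' @export
feature_anova_all <- function(pairs, auc, X, metadata) {
  lines <- intersect(rownames(auc), rownames(X))
  md <- metadata[match(lines, metadata$sample), , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    feature_anova(auc[lines, pairs$compound[i]], md$type, md$subtype,
                  X[lines, pairs$feature[i]])
  })
  pairs$anova_p <- vapply(res, `[[`, 0, "p")
  pairs$untestable <- vapply(res, `[[`, TRUE, "untestable")
  pairs$anova_q <- estimate_qvalues(pairs$anova_p)
  pairs
}
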