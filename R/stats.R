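#' @importFrom stats cor cor.test lm pt coef setNames complete.cases sd as.formula
NULL

#' Spearman rank correlation with its two-sided p-value
#'
#' Midrank ties; for n <= 20 without ties the p-value comes from the exact
#' null distribution (via [stats::cor.test()]), otherwise from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: rank correlation undefined")
  rho <- cor(rank(x), rank(y))
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 20L && !has_ties) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

#' Bonferroni correction
#'
#' `p_corr = min(1, m * p)` with the family size `m` defaulting to the
#' number of tests supplied, matching a table-wide correction scope.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Family size (number of comparisons).
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

adj_r2 <- function(fit) summary(fit)$adj.r.squared

#' Nested base-composition / genome-size regression
#'
#' Fits two ordinary-least-squares models: disorder on base composition
#' (A, C, G; T dropped as the reference to break the sum-to-one
#' collinearity) and disorder on base composition plus genome size. The
#' adjusted-R-squared difference between them measures how much disorder
#' variance genome size explains once composition is allowed for, and the
#' size coefficient's t-test p-value tests its significance. The difference
#' can be negative (adjustment penalty) when size adds nothing.
#'
#' @param obs Data frame with columns `D`, `A`, `C`, `G` and `S`
#'   (genome size, kb); n >= 8.
#' @param response `"D"` (raw percent disorder, default) or `"rank"`
#'   (rank-transformed disorder, invariant to monotone transforms).
#' @return Object of class `NestedModelResult`: list with `r2_B`, `r2_BS`,
#'   `delta_r2`, `p_size`, `n`, `response`.
#' @export
nested_size_model <- function(obs, response = c("D", "rank")) {
  response <- match.arg(response)
  need <- c("D", "A", "C", "G", "S")
  if (!all(need %in% names(obs)))
    stop("observations need columns D, A, C, G, S")
  obs <- obs[complete.cases(obs[need]), need]
  n <- nrow(obs)
  if (n < 8L) stop("need at least 8 complete observations for the nested fit")
  obs$.y <- if (response == "rank") rank(obs$D) else obs$D
  fit_b <- lm(.y ~ A + C + G, data = obs)
  fit_bs <- lm(.y ~ A + C + G + S, data = obs)
  co <- coef(fit_bs)
  if (anyNA(co))
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(names(co)[is.na(co)], collapse = ", ")))
  p_size <- summary(fit_bs)$coefficients["S", "Pr(>|t|)"]
  structure(
    list(r2_B = adj_r2(fit_b), r2_BS = adj_r2(fit_bs),
         delta_r2 = adj_r2(fit_bs) - adj_r2(fit_b),
         p_size = p_size, n = n, response = response),
    class = "NestedModelResult")
}

#' @export
print.NestedModelResult <- function(x, ...) {
  cat(sprintf(
    "<NestedModelResult (n=%d, %s): R2_B=%.3f R2_BS=%.3f dR2=%.3f p_size=%.3g>\n",
    x$n, x$response, x$r2_B, x$r2_BS, x$delta_r2, x$p_size))
  invisible(x)
}

#' Assemble the per-genome observation table
#'
#' Joins genome metadata, the disorder table and the composition table into
#' the observation frame all statistical analyses run on. Genome size is
#' reported in kb.
#'
#' @param genomes List of `GenomeRecord` objects (the analysis set).
#' @param disorder Result of [disorder_table()].
#' @param composition Result of [composition_table()].
#' @return Data frame with columns `accession`, `D`, `S`, `A`, `C`, `G`,
#'   `T`, `A4`, `C4`, `G4`, `T4`, `overlap_fraction`, `family`,
#'   `baltimore_type`, `host_category`, `n_proteins`, `total_residues`.
#' @export
make_observations <- function(genomes, disorder, composition) {
  meta <- do.call(rbind, lapply(genomes, function(g) data.frame(
    accession = g$accession, family = g$family,
    baltimore_type = g$baltimore_type, host_category = g$host_category,
    S = g$genome_size / 1000, stringsAsFactors = FALSE)))
  obs <- merge(meta, disorder[c("accession", "D", "N", "total_residues")],
               by = "accession")
  obs <- merge(obs, composition, by = "accession")
  names(obs)[names(obs) == "N"] <- "n_proteins"
  obs
}

summarise_one_group <- function(d, min_n_cor = 3L, min_n_model = 8L) {
  res <- data.frame(
    N = nrow(d),
    mean_S = mean(d$S), sd_S = if (nrow(d) >= 2L) sd(d$S) else NA_real_,
    mean_D = mean(d$D), sd_D = if (nrow(d) >= 2L) sd(d$D) else NA_real_,
    min_D = min(d$D), max_D = max(d$D), range_D = max(d$D) - min(d$D),
    spearman_rho = NA_real_, spearman_p = NA_real_,
    r2_B = NA_real_, r2_BS = NA_real_, delta_r2 = NA_real_,
    p_size = NA_real_)
  if (nrow(d) >= min_n_cor &&
      length(unique(d$S)) > 1L && length(unique(d$D)) > 1L) {
    sp <- spearman_cor(d$S, d$D)
    res$spearman_rho <- sp$rho
    res$spearman_p <- sp$p
  }
  if (nrow(d) >= min_n_model) {
    nm <- tryCatch(nested_size_model(d), error = function(e) NULL)
    if (!is.null(nm)) {
      res$r2_B <- nm$r2_B; res$r2_BS <- nm$r2_BS
      res$delta_r2 <- nm$delta_r2; res$p_size <- nm$p_size
    }
  }
  res
}

#' Grouped survey summaries
#'
#' Per-group sample size, mean and standard deviation of genome size and
#' disorder, Spearman correlation of disorder with size, and the nested
#' base-composition/size model, with Bonferroni correction applied across
#' the groups of the table (its own correction scope). For host-level
#' tables the disorder range is reported and an externally supplied host
#' proteome disorder table (literature constants) can be joined.
#'
#' @param obs Observation frame from [make_observations()].
#' @param group_by One of `"family"`, `"baltimore_type"`, `"host_category"`.
#' @param host_table Optional data frame with columns `host_category`,
#'   `host_mean`, `host_min`, `host_max` to join (host tables only).
#' @param groups Optional character vector restricting and ordering the
#'   groups (e.g. the tabulated families of a `SurveySet`).
#' @return Data frame, one row per group, with Bonferroni-corrected
#'   `spearman_p_corrected` and `p_size_corrected` columns.
#' @export
group_summaries <- function(obs,
                            group_by = c("family", "baltimore_type",
                                         "host_category"),
                            host_table = NULL, groups = NULL) {
  group_by <- match.arg(group_by)
  if (!is.null(groups)) obs <- obs[obs[[group_by]] %in% groups, ]
  if (nrow(obs) == 0L) stop("no observations left for the requested groups")
  pieces <- split(obs, obs[[group_by]], drop = TRUE)
  tab <- do.call(rbind, lapply(pieces, summarise_one_group))
  tab <- cbind(group = names(pieces), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  m <- nrow(tab)
  tab$spearman_p_corrected <- bonferroni(tab$spearman_p, m)
  tab$p_size_corrected <- bonferroni(tab$p_size, m)
  if (group_by == "host_category" && !is.null(host_table)) {
    ht <- host_table
    names(ht)[names(ht) == "host_category"] <- "group"
    tab <- merge(tab, ht, by = "group", all.x = TRUE, sort = FALSE)
  }
  tab[order(tab$group), , drop = FALSE]
}

#' Adjusted R-squared across predictor sets
#'
#' Fits one OLS model per predictor set on the common complete rows and
#' tabulates the adjusted R-squared of each, quantifying how much disorder
#' variance each combination of factors accounts for. Categorical
#' predictors (`family`, `baltimore_type`, `host_category`) are entered as
#' factors with a reference level.
#'
#' @param obs Observation frame from [make_observations()].
#' @param specs Named list of character vectors of column names; the
#'   default ladder covers bases, size, type, host, family and the
#'   composition+size and family+composition combinations. An empty vector
#'   is the intercept-only model (adjusted R-squared 0).
#' @param response `"D"` or `"rank"` (the latter matching a
#'   rank-of-disorder response).
#' @return Object of class `VarianceAttribution`: data frame with
#'   `spec_name`, `predictors`, `adj_r2`, `n`, sorted by decreasing
#'   adjusted R-squared.
#' @export
variance_attribution <- function(obs, specs = NULL,
                                 response = c("D", "rank")) {
  response <- match.arg(response)
  if (is.null(specs))
    specs <- list(
      bases = c("A", "C", "G"),
      size = "S",
      type = "baltimore_type",
      host = "host_category",
      family = "family",
      bases_size = c("A", "C", "G", "S"),
      family_bases = c("family", "A", "C", "G"))
  cols <- unique(unlist(specs))
  unknown <- setdiff(cols, names(obs))
  if (length(unknown))
    stop(sprintf("unknown column(s) in predictor specs: %s",
                 paste(unknown, collapse = ", ")))
  d <- obs[complete.cases(obs[c("D", cols)]), , drop = FALSE]
  for (cc in intersect(cols, c("family", "baltimore_type", "host_category")))
    d[[cc]] <- factor(d[[cc]])
  d$.y <- if (response == "rank") rank(d$D) else d$D
  r2 <- vapply(specs, function(sp) {
    # a single-level factor carries no information; drop it from the fit
    sp <- Filter(function(cc) !is.factor(d[[cc]]) ||
                   nlevels(droplevels(d[[cc]])) > 1L, sp)
    fml <- if (length(sp) == 0L) .y ~ 1 else
      as.formula(paste(".y ~", paste(sp, collapse = " + ")))
    adj_r2(lm(fml, data = d))
  }, numeric(1))
  out <- data.frame(
    spec_name = names(specs),
    predictors = vapply(specs, function(sp)
      if (length(sp)) paste(sp, collapse = "+") else "(intercept)",
      character(1)),
    adj_r2 = unname(r2), n = nrow(d), stringsAsFactors = FALSE)
  out <- out[order(-out$adj_r2), ]
  rownames(out) <- NULL
  class(out) <- c("VarianceAttribution", "data.frame")
  out
}

#' Disorder-composition correlations at both site classes
#'
#' Spearman correlation of percent disorder with the fraction of each base,
#' at all sites and at four-fold degenerate synonymous third positions:
#' eight rows (4 bases x 2 site classes).
#'
#' @param obs Observation frame with `D`, `A`..`T` and `A4`..`T4`.
#' @return Data frame with columns `base`, `site_class`, `rho`, `p`, `n`.
#' @export
composition_disorder_correlations <- function(obs) {
  rows <- list()
  for (cls in c("all", "fourfold")) {
    for (b in c("A", "C", "G", "T")) {
      col <- if (cls == "all") b else paste0(b, "4")
      sp <- spearman_cor(obs[[col]], obs$D)
      rows[[length(rows) + 1L]] <- data.frame(
        base = b, site_class = cls, rho = sp$rho, p = sp$p, n = sp$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
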