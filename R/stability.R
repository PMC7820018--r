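#' Subjects x measurements matrix
#'
#' The unit of every ICC computation: n subjects (rows) by k repeated
#' measurement columns (timepoints, protocols or scanners) for one feature.
#' Rows containing any missing cell are dropped (complete-case) with a
#' message; at least 2 rows and 2 columns must remain.
#'
#' @param values numeric matrix (or coercible).
#' @param subjects,columns optional dimnames.
#' @return a numeric matrix of class `measurement_matrix`.
#' @export
measurement_matrix <- function(values, subjects = NULL, columns = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (!is.null(subjects)) rownames(m) <- subjects
  if (!is.null(columns)) colnames(m) <- columns
  drop <- !stats::complete.cases(m)
  if (any(drop)) {
    message("dropping ", sum(drop), " incomplete row(s) before analysis")
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need >= 2 complete subjects (rows), have ", nrow(m))
  if (ncol(m) < 2L) stop("need >= 2 measurement columns, have ", ncol(m))
  class(m) <- c("measurement_matrix", class(m))
  m
}

#' Two-way ANOVA decomposition of a subjects x measurements matrix
#'
#' Explicit-sum decomposition: `SS_rows = k * sum((rowmean - grand)^2)`,
#' `SS_cols = n * sum((colmean - grand)^2)`, and `SS_error` summed directly
#' over the interaction residuals `y - rowmean - colmean + grand` (equal to
#' `SS_total - SS_rows - SS_cols`, but stable when per-column offsets dwarf
#' the subject signal), with degrees of freedom (n-1), (k-1) and
#' (n-1)(k-1). These are the mean squares entering the consistency ICC.
#'
#' @param m numeric matrix, n >= 2 rows (subjects) by k >= 2 columns.
#' @return list with `ms_rows`, `ms_cols`, `ms_error`, the sums of squares
#'   and degrees of freedom, plus `n` and `k`.
#' @export
anova_two_way <- function(m) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("matrix must be at least 2 x 2 (got ", n, " x ", k, ")")
  if (anyNA(m)) stop("matrix contains missing cells; use measurement_matrix()")
  g <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - g)^2)
  ss_cols <- n * sum((cm_ - g)^2)
  # interaction residuals directly: numerically robust under large
  # per-column offsets (no catastrophic cancellation)
  ss_error <- sum((m - outer(rm_, cm_, "+") + g)^2)
  ss_total <- ss_rows + ss_cols + ss_error
  list(ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
       ss_total = ss_total,
       df_rows = n - 1L, df_cols = k - 1L, df_error = (n - 1L) * (k - 1L),
       ms_rows = ss_rows / (n - 1L),
       ms_cols = ss_cols / (k - 1L),
       ms_error = ss_error / ((n - 1L) * (k - 1L)),
       n = n, k = k)
}

# Fast internal path: (icc, p) from a complete matrix; NA sentinel when the
# denominator vanishes (constant matrix).
icc3_fast <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - g)^2)
  ss_error <- sum((m - outer(rm_, cm_, "+") + g)^2)
  msr <- ss_rows / (n - 1)
  mse <- ss_error / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse
  if (den <= 0) return(c(NA_real_, NA_real_))
  icc <- (msr - mse) / den
  p <- if (mse > 0) stats::pf(msr / mse, n - 1, (n - 1) * (k - 1),
                              lower.tail = FALSE)
       else if (msr > 0) 0 else NA_real_
  c(icc, p)
}

#' Consistency intraclass correlation ICC(3,1)
#'
#' The two-way mixed-effects, consistency, single-measurement intraclass
#' correlation: `(MS_R - MS_E) / (MS_R + (k - 1) MS_E)`, where `MS_R` and
#' `MS_E` are the row (subject) and error mean squares of [anova_two_way()]
#' and k is the number of measurement columns. Systematic per-column
#' offsets do not affect it (consistency, not absolute agreement). For a
#' constant matrix the coefficient is undefined and returned as `NA` (the
#' documented sentinel) rather than an error. The estimate always lies in
#' `[-1/(k-1), 1]`.
#'
#' @param m a [measurement_matrix()] or plain complete numeric matrix.
#' @return object of class `icc3`: list with `icc`, `p_value` (row-effect
#'   F test), `f`, `n`, `k` and the underlying `anova` decomposition.
#' @export
icc3 <- function(m) {
  m <- unclass(as.matrix(m))
  dec <- anova_two_way(m)
  den <- dec$ms_rows + (dec$k - 1) * dec$ms_error
  if (den <= 0) {
    icc <- NA_real_; f <- NA_real_; p <- NA_real_
  } else {
    icc <- (dec$ms_rows - dec$ms_error) / den
    if (dec$ms_error > 0) {
      f <- dec$ms_rows / dec$ms_error
      p <- stats::pf(f, dec$df_rows, dec$df_error, lower.tail = FALSE)
    } else {
      f <- Inf
      p <- if (dec$ms_rows > 0) 0 else NA_real_
    }
  }
  structure(list(icc = icc, p_value = p, f = f, n = dec$n, k = dec$k,
                 anova = dec), class = "icc3")
}

#' @export
print.icc3 <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %s  (n = %d subjects, k = %d measurements, p = %s)\n",
              if (is.na(x$icc)) "undefined (constant matrix)"
              else format(x$icc, digits = 4),
              x$n, x$k,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Classify an ICC (or Spearman rho) value
#'
#' `good` iff value >= 0.90, `moderate` iff 0.75 < value < 0.90, `poor`
#' iff value <= 0.75. An undefined (NA) estimate is conservatively
#' classified `poor`. The boundary convention (0.90 itself is good, 0.75
#' itself is poor) is applied everywhere and configurable.
#'
#' @param value numeric vector of ICC values (NA allowed).
#' @param good,moderate class boundaries.
#' @return character vector in \{"good", "moderate", "poor"\}.
#' @export
classify_icc <- function(value, good = 0.90, moderate = 0.75) {
  out <- ifelse(is.na(value), "poor",
                ifelse(value >= good, "good",
                       ifelse(value > moderate, "moderate", "poor")))
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; monotone
#' nondecreasing in rank, each at most 1.
#'
#' @param p numeric vector of p-values.
#' @export
fdr_correct <- function(p) stats::p.adjust(p, method = "BH")

# Compute per-feature ICC over a long table, with matrix rows defined by
# the interaction of `row_vars` and columns by `col_var`. Returns one row
# per feature.
icc_by_feature <- function(ft, row_vars, col_var, experiment,
                           good = 0.90, moderate = 0.75) {
  rid <- interaction(ft[row_vars], drop = TRUE, lex.order = TRUE)
  cid <- factor(ft[[col_var]])
  fid <- factor(ft$feature, levels = unique(ft$feature))
  n <- nlevels(rid); k <- nlevels(cid); nf <- nlevels(fid)
  if (k < 2L)
    stop("experiment '", experiment, "' needs >= 2 levels of '", col_var,
         "', found: ", paste(levels(cid), collapse = ", "))
  arr <- array(NA_real_, c(n, k, nf))
  arr[cbind(as.integer(rid), as.integer(cid), as.integer(fid))] <- ft$value
  icc <- numeric(nf); pv <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- arr[, , f, drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, n, k)
    ok <- stats::complete.cases(m)
    if (sum(ok) < 2L) {
      missing_cells <- which(colSums(is.na(m)) == n)
      stop("feature '", levels(fid)[f], "', experiment '", experiment,
           "': fewer than 2 complete rows",
           if (length(missing_cells))
             paste0(" (column(s) entirely missing: ",
                    paste(levels(cid)[missing_cells], collapse = ", "), ")"))
    }
    r <- icc3_fast(m[ok, , drop = FALSE])
    icc[f] <- r[1]; pv[f] <- r[2]
  }
  data.frame(feature = levels(fid), experiment = experiment, icc = icc,
             classification = classify_icc(icc, good, moderate),
             p_value = pv, p_adj = fdr_correct(pv),
             stringsAsFactors = FALSE)
}

check_feature_table <- function(ft) {
  need <- c("subject", "scanner", "protocol", "timepoint", "feature", "value")
  if (!is.data.frame(ft) || !all(need %in% names(ft)))
    stop("feature table must have columns ", paste(need, collapse = ", "))
  invisible(ft)
}

# Median-of-experiments summary rows appended to a per-experiment result.
median_summary_rows <- function(res, label, good = 0.90, moderate = 0.75) {
  med <- tapply(res$icc, res$feature, stats::median, na.rm = TRUE)
  data.frame(feature = names(med), experiment = label, icc = as.numeric(med),
             classification = classify_icc(as.numeric(med), good, moderate),
             p_value = NA_real_, p_adj = NA_real_, stringsAsFactors = FALSE)
}

#' Test-retest repeatability
#'
#' Per feature, ICC(3,1) with timepoints as the measurement columns: one
#' result per scanner (rows = subject x protocol instances) plus a pooled
#' result over all scanners (rows = subject x protocol x scanner). For a
#' single-scanner, single-protocol test-retest cohort the rows reduce to
#' the subjects.
#'
#' @param ft long-format feature table
#'   (`subject, scanner, protocol, timepoint, feature, value`).
#' @param good,moderate classification boundaries.
#' @return `data.frame` with columns
#'   `feature, experiment, icc, classification, p_value, p_adj`.
#' @export
repeatability <- function(ft, good = 0.90, moderate = 0.75) {
  check_feature_table(ft)
  tps <- unique(ft$timepoint)
  if (length(tps) < 2L)
    stop("repeatability needs 2 timepoints; found only: ",
         paste(tps, collapse = ", "))
  scanners <- unique(ft$scanner)
  out <- lapply(scanners, function(sc)
    icc_by_feature(ft[ft$scanner == sc, ], c("subject", "protocol"),
                   "timepoint", paste0("repeatability_", sc), good, moderate))
  out <- do.call(rbind, out)
  if (length(scanners) > 1L)
    out <- rbind(out, icc_by_feature(ft, c("subject", "protocol", "scanner"),
                                     "timepoint", "repeatability_pooled",
                                     good, moderate))
  out
}

#' Intra-scanner reproducibility
#'
#' Per scanner, ICC with the protocols as the k measurement columns (rows =
#' subject x timepoint instances); the reported per-feature value is the
#' median over the scanners, appended as experiment
#' `"intra_scanner_median"`.
#'
#' @inheritParams repeatability
#' @export
intra_scanner <- function(ft, good = 0.90, moderate = 0.75) {
  check_feature_table(ft)
  scanners <- unique(ft$scanner)
  res <- do.call(rbind, lapply(scanners, function(sc)
    icc_by_feature(ft[ft$scanner == sc, ], c("subject", "timepoint"),
                   "protocol", paste0("intra_", sc), good, moderate)))
  rbind(res, median_summary_rows(res, "intra_scanner_median", good, moderate))
}

#' Inter-scanner reproducibility
#'
#' Per protocol, ICC with the scanners as the k measurement columns (rows =
#' subject x timepoint instances); the reported per-feature value is the
#' median over the protocols, appended as experiment
#' `"inter_scanner_median"`.
#'
#' @inheritParams repeatability
#' @export
inter_scanner <- function(ft, good = 0.90, moderate = 0.75) {
  check_feature_table(ft)
  protos <- unique(ft$protocol)
  res <- do.call(rbind, lapply(protos, function(p)
    icc_by_feature(ft[ft$protocol == p, ], c("subject", "timepoint"),
                   "scanner", paste0("inter_", p), good, moderate)))
  rbind(res, median_summary_rows(res, "inter_scanner_median", good, moderate))
}

#' Clinical multi-protocol reproducibility
#'
#' ICC across acquisition protocols over the cohort subjects: by default
#' all protocols present (k = 3 in the designed clinical layout); with
#' `pair`, only the two named protocols are compared (e.g. the
#' contrast-medium contrast WBCECT2 vs NCCTT2, or the slice-thickness
#' contrast BLDCT5 vs WBCECT2).
#'
#' @inheritParams repeatability
#' @param pair optional character(2) protocol labels.
#' @export
clinical_reproducibility <- function(ft, pair = NULL, good = 0.90,
                                     moderate = 0.75) {
  check_feature_table(ft)
  protos <- unique(ft$protocol)
  if (!is.null(pair)) {
    if (length(pair) != 2L || !all(pair %in% protos))
      stop("unknown protocol label(s) ",
           paste(setdiff(pair, protos), collapse = ", "),
           "; available: ", paste(protos, collapse = ", "))
    ft <- ft[ft$protocol %in% pair, ]
    label <- paste0("clinical_", pair[1], "_vs_", pair[2])
  } else {
    label <- "clinical_all_protocols"
  }
  icc_by_feature(ft, c("subject", "timepoint"), "protocol", label,
                 good, moderate)
}

#' Spearman collinearity of features with tumor volume
#'
#' Per protocol, the Spearman rank correlation (average ranks on ties)
#' between each feature and the per-subject gross tumor volume; the
#' reported rho is the median over the protocols. Classification mirrors
#' the ICC bands: good rho >= 0.9, moderate 0.75 < rho < 0.9, poor
#' rho <= 0.75.
#'
#' @inheritParams repeatability
#' @param volumes named numeric vector of tumor volumes (cm^3) keyed by
#'   subject; required for every subject in `ft`.
#' @return `data.frame` with per-protocol rho columns, the median `rho`
#'   and its classification.
#' @export
volume_collinearity <- function(ft, volumes, good = 0.90, moderate = 0.75) {
  check_feature_table(ft)
  subs <- unique(ft$subject)
  if (!all(subs %in% names(volumes)))
    stop("missing tumor volume for subject(s): ",
         paste(utils::head(setdiff(subs, names(volumes)), 5), collapse = ", "))
  protos <- unique(ft$protocol)
  fid <- factor(ft$feature, levels = unique(ft$feature))
  rho <- sapply(protos, function(p) {
    sel <- ft$protocol == p
    vapply(split(seq_len(nrow(ft))[sel], droplevels(fid[sel])), function(ix)
      stats::cor(ft$value[ix], volumes[ft$subject[ix]], method = "spearman"),
      numeric(1))[levels(fid)]
  })
  rho <- matrix(rho, nrow = nlevels(fid),
                dimnames = list(levels(fid), protos))
  med <- apply(rho, 1, stats::median, na.rm = TRUE)
  out <- data.frame(feature = levels(fid), rho = as.numeric(med),
                    classification = classify_icc(as.numeric(med),
                                                  good, moderate),
                    stringsAsFactors = FALSE)
  for (p in protos) out[[paste0("rho_", p)]] <- rho[, p]
  out
}

#' Commonality (Venn) analysis of stable-feature sets
#'
#' Given named per-experiment results, computes every Venn region of the
#' feature sets that reach the requested classification level.
#'
#' @param results named list; each element either a character vector of
#'   features or a `data.frame` with `feature` and `classification`.
#' @param level classification level defining membership (default "good").
#' @return list with `sets` (the input sets), `regions` (per-region member
#'   lists, names like `"A&B"`), and `counts`.
#' @export
commonality <- function(results, level = "good") {
  sets <- lapply(results, function(r) {
    if (is.character(r)) unique(r)
    else unique(r$feature[r$classification == level])
  })
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) stop("'results' must be a named list")
  all_feats <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_feats %in% s,
                   logical(length(all_feats)))
  member <- matrix(member, nrow = length(all_feats),
                   dimnames = list(all_feats, nm))
  regions <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_along(nm) - 1)))
    key <- paste(nm[inset], collapse = "&")
    hit <- apply(member, 1, function(row) all(row[inset]) && !any(row[!inset]))
    regions[[key]] <- all_feats[hit]
  }
  list(sets = sets, regions = regions,
       counts = vapply(regions, length, integer(1)))
}

#' Select the repeatable-and-reproducible feature set
#'
#' Step 1 keeps features whose median ICC meets `icc_threshold` in both the
#' repeatability group and the reproducibility group (median taken over the
#' experiment rows supplied in each group). Step 2 removes features whose
#' median Spearman correlation with tumor volume exceeds `rho_threshold` in
#' absolute value. The result is ordered by decreasing overall median ICC
#' (median over all supplied experiments) and tagged TA / LOG / WF by
#' filter category.
#'
#' @param repeatability_results,reproducibility_results stability
#'   `data.frame`s (rows from one or more experiments; summary `_median`
#'   rows are excluded from pooling automatically).
#' @param collinearity optional [volume_collinearity()] result; `NULL`
#'   skips the volume filter.
#' @param icc_threshold,rho_threshold selection thresholds (default 0.9).
#' @param inclusive if `TRUE` (default) an ICC exactly at the threshold is
#'   kept, matching the classification boundary convention.
#' @return `data.frame` of class `stable_set`, ordered by decreasing
#'   overall median ICC, with columns `feature, category, median_icc,
#'   median_repeatability, median_reproducibility, rho`.
#' @export
select_stable <- function(repeatability_results, reproducibility_results,
                          collinearity = NULL,
                          icc_threshold = 0.9, rho_threshold = 0.9,
                          inclusive = TRUE) {
  pool <- function(res) {
    res <- res[!grepl("_median$", res$experiment), ]
    tapply(res$icc, res$feature, stats::median, na.rm = TRUE)
  }
  med_rep <- pool(repeatability_results)
  med_rpr <- pool(reproducibility_results)
  feats <- intersect(names(med_rep), names(med_rpr))
  all_icc <- rbind(
    repeatability_results[!grepl("_median$", repeatability_results$experiment),
                          c("feature", "icc")],
    reproducibility_results[!grepl("_median$",
                                   reproducibility_results$experiment),
                            c("feature", "icc")])
  overall <- tapply(all_icc$icc, all_icc$feature, stats::median, na.rm = TRUE)
  keep <- if (inclusive)
    med_rep[feats] >= icc_threshold & med_rpr[feats] >= icc_threshold
  else med_rep[feats] > icc_threshold & med_rpr[feats] > icc_threshold
  keep[is.na(keep)] <- FALSE
  sel <- feats[keep]
  rho <- rep(NA_real_, length(sel))
  names(rho) <- sel
  if (!is.null(collinearity)) {
    rho_all <- stats::setNames(collinearity$rho, collinearity$feature)
    rho <- rho_all[sel]
    sel <- sel[is.na(rho) | abs(rho) <= rho_threshold]
    rho <- rho[sel]
  }
  out <- data.frame(feature = sel,
                    category = feature_category(sel),
                    median_icc = as.numeric(overall[sel]),
                    median_repeatability = as.numeric(med_rep[sel]),
                    median_reproducibility = as.numeric(med_rpr[sel]),
                    rho = as.numeric(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$median_icc, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("stable_set", class(out))
  out
}

#' Per-category summary of a stable feature set
#'
#' Groups the selected features by TA / LOG / WF and reports the member
#' count with the median, mean and sample standard deviation (n - 1
#' denominator) of their overall median ICCs. A single-member category gets
#' sd 0 with a note. Values print rounded to 3 decimals.
#'
#' @param stable a `stable_set` (or any data.frame with `category` and
#'   `median_icc`).
#' @return `data.frame` of class `category_summary` with columns
#'   `category, n, median_icc, mean_icc, sd_icc`.
#' @export
category_summary <- function(stable) {
  stopifnot(all(c("category", "median_icc") %in% names(stable)))
  cats <- split(stable$median_icc, stable$category)
  out <- data.frame(
    category = names(cats),
    n = vapply(cats, length, integer(1)),
    median_icc = vapply(cats, stats::median, numeric(1)),
    mean_icc = vapply(cats, mean, numeric(1)),
    sd_icc = vapply(cats, function(v)
      if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
    stringsAsFactors = FALSE)
  if (any(out$n == 1L))
    message("category with a single member: sd reported as 0")
  rownames(out) <- NULL
  class(out) <- c("category_summary", class(out))
  out
}

#' @export
print.category_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$median_icc <- round(y$median_icc, digits)
  y$mean_icc <- round(y$mean_icc, digits)
  y$sd_icc <- round(y$sd_icc, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Spearman correlation matrix between features
#'
#' Symmetric, unit-diagonal Spearman correlation matrix between feature
#' value vectors taken across all observations of the table. The default
#' subset is the top `top` features by median repeatability ICC when a
#' repeatability result is supplied, otherwise all features.
#'
#' @inheritParams repeatability
#' @param features optional character vector of feature ids.
#' @param top size of the default top-repeatability subset.
#' @param repeatability_results optional [repeatability()] result used to
#'   rank features.
#' @export
feature_correlation_matrix <- function(ft, features = NULL, top = 50,
                                       repeatability_results = NULL) {
  check_feature_table(ft)
  if (is.null(features)) {
    if (!is.null(repeatability_results)) {
      med <- sort(tapply(repeatability_results$icc,
                         repeatability_results$feature,
                         stats::median, na.rm = TRUE), decreasing = TRUE)
      features <- utils::head(names(med), top)
    } else features <- unique(ft$feature)
  }
  sub <- ft[ft$feature %in% features, ]
  key <- interaction(sub$subject, sub$scanner, sub$protocol, sub$timepoint,
                     drop = TRUE)
  wide <- matrix(NA_real_, nlevels(key), length(features),
                 dimnames = list(levels(key), features))
  wide[cbind(as.integer(key), match(sub$feature, features))] <- sub$value
  stats::cor(wide, method = "spearman", use = "pairwise.complete.obs")
}
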