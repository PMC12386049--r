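COMPOUND_CATEGORIES <- c("phenolic acid", "dihydrochalcone", "flavanol",
                         "flavonol")

#' Read a compound quantification table
#'
#' The CSV schema is one row per compound: `compound`, `category`,
#' `rt_min` (retention time), then a `mean_<condition>` / `sd_<condition>`
#' column pair per extraction condition (here 6 conditions: 40 and 50 deg C,
#' each with no enzyme, 0.5% or 1% cellulase). Missing quantifications
#' (below detection) are written `-` or left empty and preserved as `NA`,
#' never silently zeroed.
#'
#' The packaged fixture `table2_phenolics.csv` holds the 17-compound hull
#' phenolic profile; load it with
#' `read_compound_table(system.file("extdata", "table2_phenolics.csv",
#' package = "phenolflux"))`.
#'
#' @param path CSV path.
#' @return Object of class `compound_table`: `compounds` (data frame with
#'   name, category, rt_min), `mean` and `sd` (compound x condition
#'   matrices, ug/g), `conditions` (data frame with label, temperature_C,
#'   enzyme), `missing_report` (per-compound missing counts).
#' @export
read_compound_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("-", "", "NA"))
  required <- c("compound", "category", "rt_min")
  if (!all(required %in% names(raw))) {
    stop("compound table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  mean_cols <- grep("^mean_", names(raw), value = TRUE)
  sd_cols <- grep("^sd_", names(raw), value = TRUE)
  labels <- sub("^mean_", "", mean_cols)
  if (!length(labels) || !setequal(labels, sub("^sd_", "", sd_cols))) {
    stop("mean_/sd_ column pairs are inconsistent", call. = FALSE)
  }
  sd_cols <- paste0("sd_", labels)
  if (anyDuplicated(raw$compound)) {
    stop("duplicate compound names: ",
         paste(unique(raw$compound[duplicated(raw$compound)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(raw$category), COMPOUND_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown categories: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(raw[mean_cols]); colnames(m) <- labels
  s <- as.matrix(raw[sd_cols]); colnames(s) <- labels
  rownames(m) <- rownames(s) <- raw$compound
  if (any(m < 0, na.rm = TRUE) || any(s < 0, na.rm = TRUE)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  if (!identical(is.na(m), is.na(s))) {
    stop("mean/sd missingness patterns disagree", call. = FALSE)
  }
  structure(
    list(compounds = data.frame(compound = raw$compound,
                                category = raw$category,
                                rt_min = raw$rt_min,
                                stringsAsFactors = FALSE),
         mean = m, sd = s,
         conditions = parse_condition_labels(labels),
         missing_report = data.frame(compound = raw$compound,
                                     n_missing = rowSums(is.na(m)))),
    class = "compound_table"
  )
}

# labels of the form "<temp>C_<enzyme>" e.g. "40C_NE", "50C_0.5"
parse_condition_labels <- function(labels) {
  temp <- suppressWarnings(as.numeric(sub("C_.*$", "", labels)))
  enz <- sub("^.*C_", "", labels)
  data.frame(label = labels, temperature_C = temp, enzyme = enz,
             stringsAsFactors = FALSE)
}

#' Write a compound table back to its CSV schema
#' @param table A `compound_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "-", format(x, digits = 15, trim = TRUE))
  out <- table$compounds
  for (lab in colnames(table$mean)) {
    out[[paste0("mean_", lab)]] <- fmt(table$mean[, lab])
    out[[paste0("sd_", lab)]] <- fmt(table$sd[, lab])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Category counts and per-condition concentration proportions
#'
#' Counts compounds per category and computes, per condition, the share of
#' total quantified mass contributed by each category. Compounds not
#' detected under a condition contribute no mass (missing treated as 0 for
#' the proportion sums only).
#'
#' @param table A `compound_table`.
#' @return List with `counts` (named integer vector, sums to the compound
#'   total) and `proportions` (category x condition matrix, columns sum
#'   to 1).
#' @export
category_summary <- function(table) {
  counts <- table(factor(table$compounds$category,
                         levels = COMPOUND_CATEGORIES))
  m0 <- table$mean
  m0[is.na(m0)] <- 0
  by_cat <- rowsum(m0, group = factor(table$compounds$category,
                                      levels = COMPOUND_CATEGORIES))
  totals <- colSums(by_cat)
  if (any(totals <= 0)) stop("a condition has zero total mass", call. = FALSE)
  props <- sweep(by_cat, 2, totals, "/")
  list(counts = c(counts), proportions = props)
}

#' Query a compound's extremum across conditions
#'
#' @param table A `compound_table`.
#' @param compound Compound name.
#' @param statistic `"max"`, `"min"` or `"argmax"` (condition label of the
#'   maximum; `"max"`/`"min"` also return their condition).
#' @return List with `value` (ug/g), `condition` (label), `temperature_C`,
#'   `enzyme`. Missing conditions are ignored.
#' @export
condition_query <- function(table, compound,
                            statistic = c("max", "min", "argmax")) {
  statistic <- match.arg(statistic)
  i <- match(compound, table$compounds$compound)
  if (is.na(i)) stop("unknown compound: ", compound, call. = FALSE)
  vals <- table$mean[i, ]
  ok <- !is.na(vals)
  if (!any(ok)) stop("compound has no quantified condition: ", compound,
                     call. = FALSE)
  j <- if (statistic == "min") which(vals == min(vals[ok]))[1]
       else which(vals == max(vals[ok]))[1]
  cond <- table$conditions[j, ]
  list(value = unname(vals[j]), condition = cond$label,
       temperature_C = cond$temperature_C, enzyme = cond$enzyme)
}

#' Expand condition means into simulated replicates
#'
#' Raw replicate measurements behind a mean +/- SD table are rarely
#' published; this draws `n_reps` independent replicates per compound and
#' condition from Normal(mean, sd) truncated at zero, with missing entries
#' entered as 0 (not detected). Row names carry the condition label and
#' replicate index, so downstream ordination can group scores by condition.
#'
#' @param table A `compound_table`.
#' @param n_reps Replicates per condition (>= 1, default 3).
#' @param seed Integer seed (required; the expansion must be reproducible).
#' @return Numeric matrix of size (conditions * n_reps) x compounds with a
#'   `condition` attribute giving each row's condition label.
#' @export
expand_replicates <- function(table, n_reps = 3, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  labs <- colnames(table$mean)
  p <- nrow(table$mean)
  with_seed(seed, {
    rows <- lapply(labs, function(lab) {
      mu <- table$mean[, lab]; sg <- table$sd[, lab]
      mu[is.na(mu)] <- 0; sg[is.na(sg)] <- 0
      t(vapply(seq_len(n_reps),
               function(r) pmax(0, stats::rnorm(p, mu, sg)),
               numeric(p)))
    })
    X <- do.call(rbind, rows)
  })
  colnames(X) <- rownames(table$mean)
  cond <- rep(labs, each = n_reps)
  rownames(X) <- paste(cond, rep(seq_len(n_reps), length(labs)), sep = "_r")
  attr(X, "condition") <- cond
  X
}

#' Principal component analysis with autoscaling
#'
#' Centres every variable and scales it to unit variance (correlation-matrix
#' PCA) before a singular-value decomposition via [stats::prcomp()].
#' Autoscaling is the default because compound concentrations span orders of
#' magnitude; set `scale = FALSE` for covariance-matrix PCA. Constant
#' columns are dropped with a warning (they carry no direction).
#'
#' @param x Sample x variable numeric matrix (>= 3 samples).
#' @param scale Scale to unit variance (default `TRUE`).
#' @return Object of class `pca_result`: `scores`, `loadings` (orthonormal
#'   columns), `explained_pct` (sums to 100), `sdev`, `center`, `scale`,
#'   `dropped` (names of constant columns), `condition` (propagated from the
#'   input attribute, if any).
#' @export
pca_autoscaled <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(x, 2, stats::var)
  dropped <- colnames(x)[v == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x2 <- x[, v > 0, drop = FALSE]
  } else x2 <- x
  p <- stats::prcomp(x2, center = TRUE, scale. = scale)
  expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = p$x, loadings = p$rotation, explained_pct = expl,
         sdev = p$sdev, center = p$center,
         scale = if (scale) p$scale else rep(1, ncol(x2)),
         dropped = dropped, condition = attr(x, "condition")),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$explained_pct))
  cat("pca_result:", nrow(x$scores), "samples x", nrow(x$loadings),
      "variables\n")
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), x$explained_pct[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
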