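#' Mean exocarp cell width
#'
#' Width of an average exocarp cell derived from the carpel semicircle
#' circumference and the number of exocarp cells counted along it:
#' `circumference / count`. When per-replicate vectors are supplied the
#' width is computed per replicate and averaged, which matches how
#' replicate sections are usually summarized; the ratio of the two means
#' is only used when a single pooled pair is given.
#'
#' @param circumference Carpel semicircle circumference(s), um, positive.
#' @param count Exocarp cell count(s) along the measured circumference,
#'   positive (fractional counts allowed: counts averaged over sections).
#' @return Mean cell width in um (unrounded). Use [format_width()] for
#'   the conventional one-decimal display.
#' @export
mean_cell_width <- function(circumference, count) {
  circumference <- as.numeric(circumference)
  count <- as.numeric(count)
  if (length(circumference) != length(count))
    stop("circumference and count must have equal length")
  if (any(!is.finite(circumference)) || any(circumference <= 0))
    stop("circumference must be positive")
  if (any(!is.finite(count)) || any(count <= 0))
    stop("cell count must be positive")
  mean(circumference / count)
}

#' One-decimal display of a cell width
#' @param width_um Width in um.
#' @return Character scalar, width rounded to one decimal place.
#' @export
format_width <- function(width_um) sprintf("%.1f", width_um)

#' Group summary statistics
#'
#' @param n Number of biological replicates (>= 1).
#' @param mean Group mean.
#' @param sd Standard deviation across replicates (>= 0).
#' @param label Optional genotype / group label.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = NULL) {
  stopifnot(length(n) == 1L, length(mean) == 1L, length(sd) == 1L)
  if (n < 1L) stop("n must be at least 1")
  if (!is.finite(sd) || sd < 0) stop("sd must be non-negative")
  structure(list(n = as.integer(n), mean = as.numeric(mean),
                 sd = as.numeric(sd), label = label),
            class = "group_summary")
}

#' Summarize a replicate vector
#' @param x Numeric vector of replicate measurements.
#' @param label Optional group label.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x, label = NULL) {
  x <- as.numeric(x)
  group_summary(length(x), mean(x), if (length(x) > 1L) stats::sd(x) else 0,
                label = label)
}

#' Two-sample t test from summary statistics
#'
#' Student's (pooled-variance) or Welch's two-sample t test computed from
#' group means, SDs and sizes, two-sided. Student's pooled form is the
#' default, as is conventional for balanced morphometry tables. When both
#' groups have zero variance and equal means the test is degenerate and
#' `t = 0, p = 1` is returned by convention.
#'
#' @param a,b [group_summary()] objects, each with `n >= 2`.
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return A list with `t`, `df`, `p_value`, `variant` and the mean
#'   difference `a$mean - b$mean`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  variant <- match.arg(variant)
  if (a$n < 2L || b$n < 2L)
    stop("each group needs at least 2 replicates")
  diff <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0) {
    if (diff == 0)
      return(list(t = 0, df = a$n + b$n - 2L, p_value = 1,
                  variant = variant, mean_diff = 0))
    stop("zero variance in both groups with unequal means: ",
         "t statistic undefined")
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2L
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tstat <- diff / se
  list(t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       variant = variant, mean_diff = diff)
}

#' Compare two genotypes in a morphometry table
#'
#' Summarizes each measured trait per genotype and runs [two_sample_t()]
#' between two named genotypes for every shared numeric column.
#'
#' @param table A data.frame with a `genotype` column and numeric trait
#'   columns (e.g. `circumference_um`, `cell_count`, `fruit_length_mm`).
#' @param group_a,group_b Genotype labels to compare.
#' @param variant Passed to [two_sample_t()].
#' @return A data.frame with one row per trait: group means, SDs, ns, t,
#'   df and p-value.
#' @export
compare_morphometry <- function(table, group_a, group_b,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(table), "genotype" %in% names(table))
  traits <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(traits) == 0L) stop("no numeric trait columns found")
  rows <- lapply(traits, function(tr) {
    xa <- table[[tr]][table$genotype == group_a]
    xb <- table[[tr]][table$genotype == group_b]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    res <- two_sample_t(summarize_group(xa, group_a),
                        summarize_group(xb, group_b), variant)
    data.frame(trait = tr,
               mean_a = mean(xa), sd_a = stats::sd(xa), n_a = length(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb), n_b = length(xb),
               t = res$t, df = res$df, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
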