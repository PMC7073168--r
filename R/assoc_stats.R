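#' Genotype-by-CR-class contingency counts
#'
#' Cross-tabulates the cultivars carrying each observed genotype of a
#' marker against the chilling-requirement class (low / high). Missing
#' genotype calls are excluded from the counts.
#'
#' @param gt Long-format genotype table, as from [load_genotype_fixture()].
#' @param marker Marker identifier.
#' @return Integer matrix: rows = observed genotypes (sorted), columns =
#'   \code{low}, \code{high}.
#' @export
contingency_counts <- function(gt, marker) {
  rows <- gt[gt$marker == marker, ]
  if (!nrow(rows)) stop("marker '", marker, "' not in the genotype table",
                        call. = FALSE)
  rows <- rows[!is.na(rows$genotype), ]
  if (!nrow(rows)) stop("all genotype calls missing for marker '", marker,
                        "'", call. = FALSE)
  tab <- table(genotype = rows$genotype,
               cr_class = factor(rows$cr_class, levels = c("low", "high")))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Contingency chi-square test
#'
#' Pearson chi-square test of independence on a genotype x trait-class
#' count table: expected counts from the marginals, statistic
#' \code{sum((O - E)^2 / E)}, p-value from the upper chi-square tail with
#' \code{(r - 1)(c - 1)} degrees of freedom. No continuity correction is
#' applied and no exact test is substituted (matching spreadsheet CHITEST
#' behaviour); expected cells below 5 only raise a warning. Rows and
#' columns with zero totals are dropped before computing df.
#'
#' @param observed Numeric count matrix (>= 2 non-empty rows and columns).
#' @return An object of class \code{contingency_result}: \code{observed},
#'   \code{expected}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{stars}.
#' @examples
#' chi_square_test(rbind(c(10, 0), c(0, 10)))
#' @export
chi_square_test <- function(observed) {
  o <- as.matrix(observed)
  o <- o[rowSums(o) > 0, colSums(o) > 0, drop = FALSE]
  if (sum(o) == 0) stop("zero grand total", call. = FALSE)
  if (nrow(o) < 2L || ncol(o) < 2L)
    stop("need at least 2 non-empty rows and columns (df would be 0)",
         call. = FALSE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  if (any(e < 5))
    warning("expected cell count(s) below 5; chi-square approximation ",
            "may be poor", call. = FALSE)
  stat <- sum((o - e)^2 / e)
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  p <- pchisq(stat, df, lower.tail = FALSE)
  structure(
    list(observed = o, expected = e, statistic = stat, df = df,
         p_value = p, stars = significance_stars(p)),
    class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("chi-square =", format(x$statistic, digits = 5), " df =", x$df,
      " p =", format(x$p_value, digits = 3), x$stars, "\n")
  invisible(x)
}

#' Significance stars
#'
#' Strict-inequality thresholds: \code{***} for p < 0.001, \code{**} for
#' p < 0.01, \code{*} for p < 0.05, otherwise \code{ns}.
#'
#' @param p Probability (vectorized).
#' @return Character vector over \code{ns}, \code{*}, \code{**},
#'   \code{***}.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Putative low-chill-associated allele
#'
#' The allele whose frequency (allele count over twice the called
#' cultivars) exceeds the other's in low-chill cultivars by the largest
#' margin relative to high-chill cultivars; ties return \code{"tie"}.
#'
#' @param gt Long-format genotype table.
#' @param marker Marker identifier.
#' @return Single allele letter, or \code{"tie"}.
#' @export
putative_low_chill_variant <- function(gt, marker) {
  rows <- gt[gt$marker == marker & !is.na(gt$genotype), ]
  if (!nrow(rows)) stop("no genotype calls for marker '", marker, "'",
                        call. = FALSE)
  alleles <- sort(unique(unlist(strsplit(rows$genotype, "/"))))
  freq <- function(cls) {
    g <- rows$genotype[rows$cr_class == cls]
    if (!length(g))
      stop("no ", cls, "-chill calls for marker '", marker, "'",
           call. = FALSE)
    a <- unlist(strsplit(g, "/"))
    table(factor(a, alleles)) / length(a)
  }
  d <- freq("low") - freq("high")
  top <- which(d == max(d))
  if (length(top) > 1L) "tie" else alleles[top]
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' Efficiency = 10^(-1/slope) - 1, where the slope is that of the Ct
#' versus log10(template) standard curve; a perfect doubling per cycle
#' (slope -1/log10(2), about -3.32) gives efficiency 1.
#'
#' @param slope Standard-curve slope (must be negative).
#' @return Efficiency as a fraction (vectorized).
#' @examples
#' pcr_efficiency(-1 / log10(2))   # exactly 1
#' pcr_efficiency(-3.6)
#' @export
pcr_efficiency <- function(slope) {
  if (any(slope >= 0))
    stop("standard-curve slope must be negative; got ",
         paste(slope[slope >= 0], collapse = ", "), call. = FALSE)
  10^(-1 / slope) - 1
}

#' Marker-trait association table
#'
#' Runs the contingency chi-square association and putative-allele calls
#' for a set of markers.
#'
#' @param gt Long-format genotype table.
#' @param markers Markers to test; defaults to all in \code{gt}.
#' @param only_phenotyped If \code{TRUE}, restrict to cultivars with
#'   published chilling hours before testing (default uses every
#'   classified cultivar).
#' @return Data frame with one row per marker: \code{marker},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{stars},
#'   \code{low_chill_allele}.
#' @examples
#' head(association_table(load_genotype_fixture()))
#' @export
association_table <- function(gt, markers = NULL, only_phenotyped = FALSE) {
  if (only_phenotyped) gt <- gt[!is.na(gt$cr_hours), ]
  markers <- markers %||% unique(gt$marker)
  out <- lapply(markers, function(m) {
    ct <- suppressWarnings(chi_square_test(contingency_counts(gt, m)))
    data.frame(marker = m, statistic = ct$statistic, df = ct$df,
               p_value = ct$p_value, stars = ct$stars,
               low_chill_allele = putative_low_chill_variant(gt, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
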