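#' Melt-region parameters of the peach CR marker panel
#'
#' Returns the per-marker HRM analysis parameters of the 22-marker peach
#' chilling-requirement panel: primer pair, pre/post-melt baseline windows
#' (used by the two-baseline normalization) and the lower/upper limits of
#' the active melt region (used by clipping and min-max normalization).
#'
#' For a few markers the PCA-pipeline limits were tuned outside the
#' baseline windows (e.g. SNP_IGA_297497's lower limit of 63.5 sits well
#' below its 69.1-69.5 pre-melt window); this is flagged with a warning,
#' not an error.
#'
#' @return A data frame with one row per marker: \code{marker_id},
#'   \code{primer_pair}, \code{premelt_lo}, \code{premelt_hi},
#'   \code{postmelt_lo}, \code{postmelt_hi}, \code{lower_limit},
#'   \code{upper_limit} (all temperatures in degrees C).
#' @examples
#' cfg <- load_marker_fixtures()
#' cfg[cfg$marker_id == "SNP_IGA_122351", ]
#' @export
load_marker_fixtures <- function() {
  path <- system.file("extdata", "marker_melt_regions.csv",
                      package = "hrmpca", mustWork = TRUE)
  cfg <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(cfg$lower_limit < cfg$upper_limit),
            all(cfg$premelt_lo < cfg$premelt_hi),
            all(cfg$postmelt_lo < cfg$postmelt_hi))
  off <- cfg$lower_limit < cfg$premelt_lo - 1e-9 |
    cfg$upper_limit > cfg$postmelt_hi + 1e-9
  if (any(off))
    warning("melt-region limits outside the baseline windows for: ",
            paste(cfg$marker_id[off], collapse = ", "), call. = FALSE)
  cfg
}

#' Fetch one marker's melt-region configuration
#'
#' @param marker_id Marker identifier, e.g. \code{"SNP_IGA_122351"}.
#' @param fixtures Optional configuration table; defaults to
#'   [load_marker_fixtures()].
#' @return A one-row list with the fields of the configuration table.
#' @export
marker_config <- function(marker_id, fixtures = NULL) {
  cfg <- fixtures %||% suppressWarnings(load_marker_fixtures())
  i <- match(marker_id, cfg$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker_id, call. = FALSE)
  as.list(cfg[i, ])
}

#' Genotypes of the 27-cultivar peach CR panel
#'
#' Loads the reference genotype table: 15 low-chill and 12 high-chill peach
#' cultivars typed at the 11 SNP markers linked to major-effect
#' chilling-requirement QTLs. Single-letter entries in the source table
#' denote homozygotes and are expanded (\code{"G"} to \code{"G/G"});
#' heterozygote alleles are sorted so \code{"A/G"} and \code{"G/A"}
#' coincide. A trailing \code{*} in the packaged CSV marks calls validated
#' by Sanger sequencing. Chilling hours are available for 20 of the 27
#' cultivars; the class label (\code{low}/\code{high}) is always present.
#'
#' @return A long-format data frame with columns \code{cultivar},
#'   \code{cr_class} (factor, levels \code{low}, \code{high}),
#'   \code{cr_hours} (numeric, \code{NA} when unpublished), \code{marker},
#'   \code{genotype} (normalized unordered pair, \code{NA} if missing) and
#'   \code{sanger_validated} (logical).
#' @examples
#' gt <- load_genotype_fixture()
#' subset(gt, cultivar == "Okinawa" & marker == "SNP_IGA_122351")
#' @export
load_genotype_fixture <- function() {
  read_genotype_csv(system.file("extdata", "peach_cr_genotypes.csv",
                                package = "hrmpca", mustWork = TRUE))
}

#' Read a wide-format genotype table
#'
#' Parses a CSV in the same dialect as the packaged panel: columns
#' \code{cultivar}, \code{cr_class} (low/high), \code{cr_hours}, then one
#' column per marker holding genotype strings (single letters expand to
#' homozygotes; a trailing \code{*} marks Sanger validation; empty or
#' \code{NA} cells are missing calls).
#'
#' @param path CSV file path.
#' @return A long-format genotype data frame (see
#'   [load_genotype_fixture()]).
#' @export
read_genotype_csv <- function(path) {
  wide <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cultivar", "cr_class", "cr_hours")
  if (!all(need %in% names(wide)) || ncol(wide) < 4L)
    stop("genotype CSV needs cultivar, cr_class, cr_hours plus at least ",
         "one marker column", call. = FALSE)
  markers <- setdiff(names(wide), need)
  hours <- suppressWarnings(as.numeric(wide$cr_hours))
  long <- do.call(rbind, lapply(markers, function(m) {
    raw <- wide[[m]]
    data.frame(cultivar = wide$cultivar,
               cr_class = factor(wide$cr_class, levels = c("low", "high")),
               cr_hours = hours,
               marker = m,
               genotype = normalize_genotype(sub("\\*$", "", raw)),
               sanger_validated = grepl("\\*$", raw),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
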