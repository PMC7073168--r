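#' Melt-curve dataset
#'
#' Container for one marker's plate run: a shared temperature grid and one
#' raw (or normalized) fluorescence curve per sample.
#'
#' @param temperatures Numeric vector of grid temperatures (degrees C), one
#'   per fluorescence read, strictly increasing.
#' @param fluorescence Numeric matrix, reads x samples; column \code{j} is
#'   sample \code{j}'s curve on the grid. All values must be finite.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix column names.
#' @param marker_id Optional marker label carried through the pipeline.
#'
#' @return An object of class \code{melt_dataset}: a list with fields
#'   \code{marker_id}, \code{temperatures}, \code{fluorescence} and
#'   \code{sample_ids}.
#' @examples
#' tg <- seq(70, 90, by = 0.5)
#' f <- cbind(s1 = rev(seq_along(tg)), s2 = rev(seq_along(tg)) + 1)
#' melt_dataset(tg, f)
#' @export
melt_dataset <- function(temperatures, fluorescence, sample_ids = NULL,
                         marker_id = NA_character_) {
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.matrix(fluorescence)
  storage.mode(fluorescence) <- "double"
  sample_ids <- as.character(sample_ids %||% colnames(fluorescence))
  if (length(sample_ids) == 0L)
    stop("melt_dataset needs at least one sample", call. = FALSE)
  if (anyNA(temperatures) || any(!is.finite(temperatures)))
    stop("temperatures must be finite", call. = FALSE)
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (nrow(fluorescence) != length(temperatures))
    stop("fluorescence has ", nrow(fluorescence), " rows but there are ",
         length(temperatures), " temperatures", call. = FALSE)
  if (ncol(fluorescence) != length(sample_ids))
    stop("fluorescence has ", ncol(fluorescence), " columns but there are ",
         length(sample_ids), " sample ids", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(fluorescence)))
    stop("fluorescence values must all be finite", call. = FALSE)
  colnames(fluorescence) <- sample_ids
  structure(
    list(marker_id = marker_id, temperatures = temperatures,
         fluorescence = fluorescence, sample_ids = sample_ids),
    class = "melt_dataset")
}

#' @export
print.melt_dataset <- function(x, ...) {
  cat("<melt_dataset>", if (!is.na(x$marker_id)) x$marker_id else "",
      "\n  ", length(x$temperatures), " reads over ",
      sprintf("%.2f-%.2f", min(x$temperatures), max(x$temperatures)),
      " degC, ", length(x$sample_ids), " samples\n", sep = "")
  invisible(x)
}

#' Read a melt-curve plate export
#'
#' Parses the comma-separated plate-export dialect: a header row, a first
#' column of read temperatures (header \code{Temperature}) and one column of
#' raw fluorescence per sample.
#'
#' @param path Path to a CSV file.
#' @param marker_id Optional marker label to attach.
#' @return A [melt_dataset].
#' @seealso [write_melt_csv()] for the inverse.
#' @export
read_melt_csv <- function(path, marker_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("melt CSV needs a temperature column plus at least one sample",
         call. = FALSE)
  ids <- names(raw)[-1]
  if (anyDuplicated(ids))
    stop("duplicate sample header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  num <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1], j], "' at data row ", bad[1],
           ", column '", names(raw)[j], "'", call. = FALSE)
    num[, j] <- v
  }
  if (any(diff(num[, 1]) <= 0))
    stop("temperature column is not strictly increasing", call. = FALSE)
  melt_dataset(num[, 1], num[, -1, drop = FALSE], sample_ids = ids,
               marker_id = marker_id)
}

#' Write a melt-curve plate export
#'
#' Emits the same CSV dialect that [read_melt_csv()] accepts, so
#' \code{read_melt_csv(write_melt_csv(ds, f))} round-trips the numeric
#' content.
#'
#' @param ds A [melt_dataset].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_melt_csv <- function(ds, path) {
  stopifnot(inherits(ds, "melt_dataset"))
  if (length(ds$sample_ids) == 0L)
    stop("refusing to write a dataset with no samples", call. = FALSE)
  out <- data.frame(Temperature = ds$temperatures, check.names = FALSE)
  out[ds$sample_ids] <- as.data.frame(ds$fluorescence)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average per-well temperatures into one grid
#'
#' Plate exports may carry one temperature column per well; the grid
#' temperature of each fluorescence read is then the mean over wells at that
#' read.
#'
#' @param per_well_temps Numeric matrix, reads x wells.
#' @return Numeric vector of per-read mean temperatures, strictly
#'   increasing (otherwise an error asks for inspection of the export).
#' @export
average_read_temperatures <- function(per_well_temps) {
  m <- as.matrix(per_well_temps)
  if (length(m) == 0L || any(!is.finite(m)))
    stop("per-well temperature matrix must be non-empty and finite",
         call. = FALSE)
  avg <- rowMeans(m)
  if (any(diff(avg) <= 0))
    stop("averaged read temperatures are not strictly increasing; ",
         "inspect the plate export for misordered reads", call. = FALSE)
  avg
}

#' Export genotype calls as a minimal VCF
#'
#' Writes one VCF record per marker with per-sample \code{GT} fields, for
#' interoperability with standard variant tooling. Alleles are taken from
#' the calls themselves; the lexicographically first allele becomes REF.
#'
#' @param calls Named list: one element per marker, each a named character
#'   vector of diploid genotypes (\code{"A/G"} style; \code{NA} allowed).
#'   All markers must cover the same samples.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_vcf_calls <- function(calls, path) {
  if (!length(calls) || is.null(names(calls)))
    stop("'calls' must be a named list of per-marker genotype vectors",
         call. = FALSE)
  samples <- names(calls[[1]])
  lines <- c("##fileformat=VCFv4.2",
             "##source=hrmpca",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (m in names(calls)) {
    g <- normalize_genotype(calls[[m]][samples])
    al <- sort(unique(unlist(strsplit(g[!is.na(g)], "/"))))
    if (length(al) == 0L) al <- "N"
    ref <- al[1]
    alt <- if (length(al) > 1L) paste(al[-1], collapse = ",") else "."
    gt <- vapply(g, function(s) {
      if (is.na(s)) return("./.")
      paste(match(strsplit(s, "/")[[1]], al) - 1L, collapse = "/")
    }, character(1))
    lines <- c(lines, paste(c(".", "0", m, ref, alt, ".", ".", ".", "GT",
                              gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
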