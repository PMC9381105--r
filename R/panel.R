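#' Define an analyte panel
#'
#' An analyte panel lists the phosphosite-resolved analytes measured by a
#' multiplexed bead assay, together with the subset used as loading /
#' normalization controls. The control set must include `"GAPDH"`, the
#' loading control every well is normalized against.
#'
#' @param analytes Character vector of unique analyte identifiers,
#'   phosphosite-resolved where applicable (e.g. `"AKT_S473"`).
#' @param controls Character vector of control analyte identifiers; must be a
#'   subset of `analytes` and contain `"GAPDH"`.
#' @return An object of class `analyte_panel` with elements `analytes`,
#'   `controls`, `phospho` (the non-control analytes) and `size`
#'   (number of non-control analytes).
#' @examples
#' p <- analyte_panel(c("GAPDH", "AKT_S473", "ERK1_T202"))
#' p$size  # 2
#' @export
analyte_panel <- function(analytes, controls = "GAPDH") {
  analytes <- as.character(analytes)
  controls <- as.character(controls)
  if (anyDuplicated(analytes))
    stop("duplicate analyte identifiers: ",
         paste(unique(analytes[duplicated(analytes)]), collapse = ", "))
  if (!all(controls %in% analytes))
    stop("controls must be a subset of analytes; missing: ",
         paste(setdiff(controls, analytes), collapse = ", "))
  if (!"GAPDH" %in% controls)
    stop("controls must include the GAPDH loading control")
  phospho <- setdiff(analytes, controls)
  if (length(phospho) == 0L)
    stop("panel has no non-control analytes")
  structure(
    list(analytes = analytes, controls = controls,
         phospho = phospho, size = length(phospho)),
    class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat("Analyte panel:", x$size, "phospho-analytes +",
      length(x$controls), "control(s) [",
      paste(x$controls, collapse = ", "), "]\n")
  invisible(x)
}

#' Construct a perturbation matrix
#'
#' A perturbation matrix holds the signed, normalized phosphoprotein changes
#' (log2 scale, DMSO-referenced) for a set of (sample, drug) conditions over
#' one analyte panel.
#'
#' @param changes Numeric matrix, one row per (sample, drug) condition, one
#'   column per non-control analyte of `panel`.
#' @param sample Character vector of sample identifiers, one per row.
#' @param drug Character vector of drug identifiers, one per row.
#' @param panel An [analyte_panel].
#' @param sample_type Named character vector mapping each sample to
#'   `"cell_line"` or `"patient"`; defaults to `"cell_line"` for all.
#' @return An object of class `perturbation_matrix`.
#' @export
perturbation_matrix <- function(changes, sample, drug, panel,
                                sample_type = NULL) {
  changes <- as.matrix(changes)
  sample <- as.character(sample)
  drug <- as.character(drug)
  if (nrow(changes) != length(sample) || length(sample) != length(drug))
    stop("changes, sample and drug must have matching lengths")
  if (is.null(colnames(changes)))
    stop("changes must have analyte column names")
  missing <- setdiff(panel$phospho, colnames(changes))
  if (length(missing))
    stop("missing analyte column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(changes), panel$phospho)
  if (length(extra)) {
    warning("ignoring non-panel column(s): ", paste(extra, collapse = ", "))
    changes <- changes[, panel$phospho, drop = FALSE]
  }
  changes <- changes[, panel$phospho, drop = FALSE]
  if (!all(is.finite(changes)))
    stop("non-finite change values present")
  key <- paste(sample, drug, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (sample, drug) pair: ",
         gsub("\r", ", ", d, fixed = TRUE))
  }
  usamp <- unique(sample)
  if (is.null(sample_type)) {
    sample_type <- stats::setNames(rep("cell_line", length(usamp)), usamp)
  } else {
    if (!all(usamp %in% names(sample_type)))
      stop("sample_type missing entries for: ",
           paste(setdiff(usamp, names(sample_type)), collapse = ", "))
    sample_type <- sample_type[usamp]
    bad <- !sample_type %in% c("cell_line", "patient")
    if (any(bad))
      stop("sample_type values must be 'cell_line' or 'patient'")
  }
  rownames(changes) <- paste(sample, drug, sep = ":")
  structure(
    list(changes = changes, sample = sample, drug = drug,
         sample_type = sample_type, panel = panel),
    class = "perturbation_matrix")
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  cat("Perturbation matrix:", nrow(x$changes), "conditions (",
      length(unique(x$sample)), "samples x",
      length(unique(x$drug)), "drugs ),",
      ncol(x$changes), "analytes\n")
  tab <- table(x$sample_type)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.perturbation_matrix <- function(object, ...) {
  cat("Change value summary (log2 scale):\n")
  print(summary(as.vector(object$changes)))
  invisible(object)
}

#' Write a perturbation matrix to delimited text
#'
#' Layout: one row per (sample, drug) condition with columns
#' `sample, drug, sample_type, <analyte...>`. Values are written with full
#' double precision so a write/read round trip is lossless to at least 12
#' significant digits.
#'
#' @param x A [perturbation_matrix].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_perturbation_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "perturbation_matrix"))
  df <- data.frame(sample = x$sample, drug = x$drug,
                   sample_type = unname(x$sample_type[x$sample]),
                   stringsAsFactors = FALSE)
  ch <- as.data.frame(x$changes)
  # format() at 17 significant digits preserves doubles exactly
  for (j in seq_along(ch)) ch[[j]] <- formatC(ch[[j]], digits = 17,
                                              format = "g")
  utils::write.table(cbind(df, ch), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a perturbation matrix from delimited text
#'
#' Expects a header row and columns `sample`, `drug`, optionally
#' `sample_type`, and one column per non-control analyte of `panel`.
#' Missing analyte columns are an error; extra columns are dropped with a
#' warning; duplicated (sample, drug) rows are an error.
#'
#' @param path Input file path (CSV or TSV; the separator is sniffed from
#'   the header line).
#' @param panel An [analyte_panel] the table is validated against.
#' @return A [perturbation_matrix].
#' @export
read_perturbation_matrix <- function(path, panel) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  for (col in c("sample", "drug"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  st <- NULL
  if ("sample_type" %in% names(df)) {
    st <- stats::setNames(df$sample_type, df$sample)
    st <- st[!duplicated(names(st))]
  }
  acols <- setdiff(names(df), c("sample", "drug", "sample_type"))
  missing <- setdiff(panel$phospho, acols)
  if (length(missing))
    stop("missing analyte column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(acols, panel$phospho)
  if (length(extra)) {
    warning("ignoring non-panel column(s): ", paste(extra, collapse = ", "))
    acols <- setdiff(acols, extra)
  }
  m <- matrix(NA_real_, nrow(df), length(acols),
              dimnames = list(NULL, acols))
  for (j in acols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric change value at row %d, column '%s': '%s'",
                   bad[1L], j, df[[j]][bad[1L]]))
    m[, j] <- v
  }
  perturbation_matrix(m, df$sample, df$drug, panel, sample_type = st)
}
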