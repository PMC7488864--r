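#' Construct a Diamond Standard
#'
#' A Diamond Standard is the full cases-by-raters matrix of independent
#' categorical annotations from which a single-label Gold Standard is later
#' derived by a reduction. Rows are case presentations, columns are raters;
#' every cell must hold a label from the declared alphabet.
#'
#' Repeated presentations of the same case (used to measure intra-rater
#' variability) are declared explicitly through `repetition_group`: rows that
#' share a non-`NA` group value are presentations of one underlying case.
#' Duplicate case identifiers are rejected unless covered by a repetition
#' group.
#'
#' @param labels character matrix (or data.frame) of annotations, cases in
#'   rows, raters in columns.
#' @param alphabet ordered character vector of admissible labels. Defaults to
#'   the sorted set of observed labels.
#' @param case_ids case identifiers; default taken from rownames or generated.
#' @param rater_ids rater identifiers; default taken from colnames or generated.
#' @param repetition_group optional vector (length = number of rows) marking
#'   repeated presentations; `NA` for ordinary rows.
#' @param allow_missing if `TRUE`, `NA` cells are tolerated and reliability
#'   computations fall back to pairwise-complete handling.
#' @return An object of class `diamond_standard`.
#' @examples
#' d <- diamond_standard(matrix(c("A", "A", "B", "A", "B", "B"), ncol = 2),
#'                       alphabet = c("A", "B"))
#' d$n_raters
#' @export
diamond_standard <- function(labels, alphabet = NULL, case_ids = NULL,
                             rater_ids = NULL, repetition_group = NULL,
                             allow_missing = FALSE) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  if (!is.matrix(labels)) stop("`labels` must be a matrix or data.frame")
  storage.mode(labels) <- "character"
  if (nrow(labels) < 1L) stop("a Diamond Standard needs at least one case")
  if (ncol(labels) < 1L) stop("a Diamond Standard needs at least one rater")

  if (is.null(case_ids)) {
    case_ids <- rownames(labels)
    if (is.null(case_ids))
      case_ids <- sprintf("case%03d", seq_len(nrow(labels)))
  }
  if (is.null(rater_ids)) {
    rater_ids <- colnames(labels)
    if (is.null(rater_ids))
      rater_ids <- sprintf("rater%02d", seq_len(ncol(labels)))
  }
  if (length(case_ids) != nrow(labels)) stop("case_ids length mismatch")
  if (length(rater_ids) != ncol(labels)) stop("rater_ids length mismatch")

  observed <- unique(labels[!is.na(labels)])
  if (is.null(alphabet)) alphabet <- sort(observed)
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet contains duplicated labels")
  bad <- setdiff(observed, alphabet)
  if (length(bad) > 0L)
    stop("labels outside the declared alphabet: ", paste(bad, collapse = ", "))
  if (anyNA(labels) && !allow_missing)
    stop("missing annotations present; set allow_missing = TRUE for ",
         "pairwise-complete handling")

  if (!is.null(repetition_group)) {
    if (length(repetition_group) != nrow(labels))
      stop("repetition_group length mismatch")
    repetition_group <- as.character(repetition_group)
  }
  dup <- duplicated(case_ids)
  if (any(dup)) {
    covered <- !is.null(repetition_group) &&
      all(!is.na(repetition_group[case_ids %in% case_ids[dup]]))
    if (!covered)
      stop("duplicate case ids must be declared as repetitions via ",
           "`repetition_group`")
  }

  dimnames(labels) <- list(case_ids, rater_ids)
  structure(
    list(labels = labels, alphabet = alphabet,
         case_ids = case_ids, rater_ids = rater_ids,
         n_cases = nrow(labels), n_raters = ncol(labels),
         repetition_group = repetition_group,
         allow_missing = allow_missing),
    class = "diamond_standard")
}

#' @export
print.diamond_standard <- function(x, ...) {
  cat("Diamond Standard:", x$n_cases, "case presentations x",
      x$n_raters, "raters\n")
  cat("Alphabet:", paste(x$alphabet, collapse = ", "), "\n")
  if (!is.null(x$repetition_group)) {
    ng <- length(unique(stats::na.omit(x$repetition_group)))
    cat("Repetition groups:", ng, "\n")
  }
  invisible(x)
}

#' Construct a confidence matrix for a Diamond Standard
#'
#' Raters report how certain they are of each annotation on a declared ordinal
#' scale (e.g. a 6-level semantic differential from "definitely not sure" to
#' "100% certain"). The raw reports are normalised ("corrected") onto
#' \eqn{[0,1]} by a monotone map; the default is the affine rescale
#' \eqn{(raw - scale_{min})/(scale_{max} - scale_{min})}.
#'
#' @param raw numeric matrix of raw ordinal confidence reports, same shape as
#'   the annotation matrix it accompanies.
#' @param scale_min,scale_max bounds of the ordinal scale.
#' @param n_levels number of scale levels (metadata only; the correction uses
#'   the bounds).
#' @param correction either `"affine"` (map onto `[0,1]`), `"chance_floor"`
#'   (map onto `[1/n_labels, 1]`, requires `n_labels`), or a function mapping
#'   a raw numeric matrix to corrected values in `[0,1]`.
#' @param n_labels alphabet size, used only by the `"chance_floor"` correction.
#' @return An object of class `confidence_matrix` with elements `raw`,
#'   `corrected` and `scale`.
#' @examples
#' cm <- confidence_matrix(matrix(c(1, 3, 6, 6), 2), scale_min = 1, scale_max = 6)
#' cm$corrected
#' @export
confidence_matrix <- function(raw, scale_min = 1, scale_max = 6,
                              n_levels = scale_max - scale_min + 1,
                              correction = "affine", n_labels = NULL) {
  if (is.data.frame(raw)) raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("`raw` must be numeric")
  if (scale_max <= scale_min) stop("scale_max must exceed scale_min")
  if (any(raw < scale_min | raw > scale_max, na.rm = TRUE))
    stop("raw confidence outside the declared scale [",
         scale_min, ", ", scale_max, "]")
  corrected <- correct_confidence(raw, scale_min, scale_max,
                                  correction = correction, n_labels = n_labels)
  structure(
    list(raw = raw, corrected = corrected,
         scale = list(min = scale_min, max = scale_max, n_levels = n_levels),
         correction = if (is.function(correction)) "custom" else correction),
    class = "confidence_matrix")
}

#' @export
print.confidence_matrix <- function(x, ...) {
  cat("Confidence matrix:", nrow(x$raw), "x", ncol(x$raw),
      sprintf("(scale [%g, %g], %d levels, correction: %s)\n",
              x$scale$min, x$scale$max, x$scale$n_levels, x$correction))
  invisible(x)
}

#' Correct raw ordinal confidence reports onto [0, 1]
#'
#' @inheritParams confidence_matrix
#' @return Numeric matrix (or vector) of corrected confidences in `[0,1]`.
#' @examples
#' correct_confidence(c(1, 3, 6), 1, 6) # 0, 0.4, 1
#' @export
correct_confidence <- function(raw, scale_min = 1, scale_max = 6,
                               correction = "affine", n_labels = NULL) {
  if (any(raw < scale_min | raw > scale_max, na.rm = TRUE))
    stop("raw confidence outside the declared scale")
  if (is.function(correction)) {
    out <- correction(raw)
  } else {
    out <- switch(match.arg(correction, c("affine", "chance_floor")),
      affine = (raw - scale_min) / (scale_max - scale_min),
      chance_floor = {
        if (is.null(n_labels) || n_labels < 2)
          stop("chance_floor correction needs `n_labels` >= 2")
        lo <- 1 / n_labels
        lo + (1 - lo) * (raw - scale_min) / (scale_max - scale_min)
      })
  }
  if (any(out < -1e-12 | out > 1 + 1e-12, na.rm = TRUE))
    stop("corrected confidences must lie in [0, 1]")
  pmin(pmax(out, 0), 1)
}

#' Read a Diamond Standard (and optional confidence matrix) from delimited text
#'
#' The annotation file must have a `case_id` first column, an optional
#' `repetition_group` column, and one column per rater. The confidence file,
#' if given, must have exactly the same layout. A schema (list, or path to a
#' YAML/JSON file) declares the label alphabet and the confidence scale.
#'
#' @param path path to the annotation CSV/TSV.
#' @param confidence_path optional path to the parallel confidence file.
#' @param schema a list with elements `alphabet` and optionally `scale`
#'   (`min`, `max`, `n_levels`), or a path to a YAML/JSON file holding it.
#' @param sep field separator; default `","`.
#' @param allow_missing passed to [diamond_standard()].
#' @return A `diamond_standard`; if `confidence_path` is given, the
#'   `confidence` attribute holds the matching `confidence_matrix` (also
#'   returned by `attr(d, "confidence")`).
#' @export
read_diamond <- function(path, confidence_path = NULL, schema = NULL,
                         sep = ",", allow_missing = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  schema <- read_schema(schema)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "case_id")
    stop("first column of the annotation file must be `case_id`")
  rep_col <- which(names(tab) == "repetition_group")
  repetition_group <- NULL
  if (length(rep_col) == 1L) {
    repetition_group <- tab[[rep_col]]
    repetition_group[repetition_group == ""] <- NA_character_
  }
  rater_cols <- setdiff(seq_along(tab), c(1L, rep_col))
  labels <- as.matrix(tab[rater_cols])
  labels[labels == ""] <- NA_character_
  d <- diamond_standard(labels, alphabet = schema$alphabet,
                        case_ids = tab$case_id,
                        rater_ids = names(tab)[rater_cols],
                        repetition_group = repetition_group,
                        allow_missing = allow_missing)
  if (!is.null(confidence_path)) {
    if (!file.exists(confidence_path))
      stop("confidence file not found: ", confidence_path)
    ctab <- utils::read.table(confidence_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, check.names = FALSE)
    crep <- which(names(ctab) == "repetition_group")
    craters <- setdiff(seq_along(ctab), c(1L, crep))
    raw <- as.matrix(ctab[craters])
    storage.mode(raw) <- "double"
    if (!identical(dim(raw), dim(d$labels)))
      stop("confidence matrix shape (", nrow(raw), " x ", ncol(raw),
           ") does not match the annotation matrix (",
           nrow(d$labels), " x ", ncol(d$labels), ")")
    sc <- schema$scale
    if (is.null(sc)) sc <- list(min = 1, max = 6, n_levels = 6)
    cm <- confidence_matrix(raw, scale_min = sc$min, scale_max = sc$max,
                            n_levels = sc$n_levels,
                            n_labels = length(d$alphabet))
    attr(d, "confidence") <- cm
  }
  d
}

#' Write a Diamond Standard (and optional confidence matrix) to CSV
#'
#' Canonical dialect: comma-separated, header row, `case_id` first column,
#' `repetition_group` second when present. `save(load(x))` round-trips
#' byte-identically.
#'
#' @param d a `diamond_standard`.
#' @param path output path for the annotation file.
#' @param confidence optional `confidence_matrix` to write alongside.
#' @param confidence_path output path for the confidence file.
#' @return `path`, invisibly.
#' @export
write_diamond <- function(d, path, confidence = NULL, confidence_path = NULL) {
  stopifnot(inherits(d, "diamond_standard"))
  tab <- data.frame(case_id = d$case_ids, stringsAsFactors = FALSE)
  if (!is.null(d$repetition_group))
    tab$repetition_group <- ifelse(is.na(d$repetition_group), "",
                                   d$repetition_group)
  tab <- cbind(tab, as.data.frame(d$labels, stringsAsFactors = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(confidence)) {
    if (is.null(confidence_path))
      stop("confidence_path required when writing a confidence matrix")
    ctab <- data.frame(case_id = d$case_ids, stringsAsFactors = FALSE)
    if (!is.null(d$repetition_group))
      ctab$repetition_group <- ifelse(is.na(d$repetition_group), "",
                                      d$repetition_group)
    ctab <- cbind(ctab, as.data.frame(confidence$raw))
    names(ctab)[(ncol(ctab) - d$n_raters + 1):ncol(ctab)] <- d$rater_ids
    utils::write.csv(ctab, confidence_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read reference labels (two-column CSV: case_id, label)
#'
#' @param path path to the reference CSV.
#' @return named character vector of labels, names = case ids.
#' @export
read_reference <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("case_id", "label") %in% names(tab)))
    stop("reference file needs columns `case_id` and `label`")
  stats::setNames(tab$label, tab$case_id)
}

# Schema: NULL, list, or path to YAML/JSON declaring alphabet + scale.
read_schema <- function(schema) {
  if (is.null(schema)) return(list(alphabet = NULL, scale = NULL))
  if (is.character(schema) && length(schema) == 1L) {
    if (!file.exists(schema)) stop("schema file not found: ", schema)
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE))
      jsonlite::read_json(schema, simplifyVector = TRUE)
    else yaml::read_yaml(schema)
  }
  if (!is.list(schema)) stop("schema must be a list or a YAML/JSON path")
  if (!is.null(schema$alphabet))
    schema$alphabet <- as.character(unlist(schema$alphabet))
  schema
}
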