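# Allowed category levels for the tumour-cohort annotation dialect. The
# dialect is strict: any value outside these levels (other than literal "NA")
# is an error, so typos like stage "T3" never pass silently.
ANNOTATION_LEVELS <- list(
  tissue        = c("NPT", "PCa"),
  subtype       = c("PEA3", "ERG", "ETS_negative"),
  pea3_gene     = c("ETV1", "ETV4", "ETV5"),
  gleason_group = c("low", "high"),
  stage         = c("pT2", "pT3")
)

#' Validate a per-sample annotation table
#'
#' Checks the tumour-cohort annotation dialect: categorical columns must take
#' only their allowed levels (or NA), numeric columns must be numeric, and
#' normal prostate tissue (NPT) samples must have NA subtype, stage and
#' Gleason group.
#'
#' @param anno data.frame with at least a `sample_id` column.
#' @return `anno`, invisibly.
#' @export
validate_annotations <- function(anno) {
  if (!is.data.frame(anno) || !"sample_id" %in% names(anno))
    stop("annotation table must contain a 'sample_id' column")
  dup <- anno$sample_id[duplicated(anno$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  for (col in names(ANNOTATION_LEVELS)) {
    if (!col %in% names(anno)) next
    vals <- anno[[col]]
    bad <- !is.na(vals) & !vals %in% ANNOTATION_LEVELS[[col]]
    if (any(bad))
      stop(sprintf("invalid %s value '%s'; allowed: %s, NA",
                   col, vals[bad][1],
                   paste(ANNOTATION_LEVELS[[col]], collapse = ", ")))
  }
  for (col in intersect(c("age_years", "psa_ng_ml"), names(anno)))
    if (!is.numeric(anno[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
  if (all(c("tissue", "subtype", "stage", "gleason_group") %in% names(anno))) {
    npt <- anno$tissue == "NPT"
    if (any(npt & (!is.na(anno$subtype) | !is.na(anno$stage) |
                     !is.na(anno$gleason_group))))
      stop("NPT samples must have NA subtype, stage and gleason_group")
  }
  invisible(anno)
}

#' Read a per-sample annotation table
#'
#' Tab-delimited, one row per sample; the literal string "NA" denotes a
#' missing value. Categorical columns are validated against the strict
#' dialect (see [validate_annotations()]).
#'
#' @param path file path.
#' @return data.frame of typed annotation records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  anno <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE, na.strings = "NA")
  validate_annotations(anno)
  anno
}

#' Write a per-sample annotation table
#'
#' @param anno annotation data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anno, path) {
  validate_annotations(anno)
  write.table(anno, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
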