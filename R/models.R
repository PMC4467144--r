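#' Construct a cell population
#'
#' A population is a labelled set of replicate sample columns with a role of
#' either `"control"` (e.g. shNeg, PNT2-Neo) or `"manipulated"` (an shRNA
#' clone/polyclonal population or an overexpressing population).
#'
#' @param label population label, e.g. `"shETV1-C1"`.
#' @param sample_ids character vector of >=1 sample (array) column ids.
#' @param role `"control"` or `"manipulated"`.
#' @return an object of class `"population"`.
#' @export
population <- function(label, sample_ids, role = c("control", "manipulated")) {
  role <- match.arg(role)
  if (!is.character(sample_ids) || length(sample_ids) < 1)
    stop("population '", label, "' needs >=1 sample id")
  structure(list(label = label, sample_ids = sample_ids, role = role),
            class = "population")
}

#' Construct a cell-line model
#'
#' One control population plus one or more manipulated populations of a single
#' cell line, targeting one ETS gene by either shRNA silencing or de novo
#' overexpression. The study design uses two manipulated populations per model.
#'
#' @param name model name, e.g. `"shETV1-LNCaP"`.
#' @param ets targeted ETS gene, `"ETV1"` or `"ETV4"`.
#' @param kind `"silencing"` or `"overexpression"`.
#' @param control a `"control"`-role [population()].
#' @param manipulated list of `"manipulated"`-role [population()]s.
#' @return an object of class `"cellline_model"`.
#' @export
cell_line_model <- function(name, ets = c("ETV1", "ETV4"),
                            kind = c("silencing", "overexpression"),
                            control, manipulated) {
  ets <- match.arg(ets)
  kind <- match.arg(kind)
  if (!inherits(control, "population") || control$role != "control")
    stop("model '", name, "': control must be a population with role 'control'")
  if (inherits(manipulated, "population")) manipulated <- list(manipulated)
  if (!length(manipulated) ||
      !all(vapply(manipulated, function(p)
        inherits(p, "population") && p$role == "manipulated", logical(1))))
    stop("model '", name,
         "': manipulated must be >=1 populations with role 'manipulated'")
  manip_ids <- unlist(lapply(manipulated, `[[`, "sample_ids"))
  overlap <- intersect(control$sample_ids, manip_ids)
  if (length(overlap))
    stop("model '", name, "': sample id(s) shared between control and ",
         "manipulated populations: ", paste(overlap, collapse = ", "))
  structure(list(name = name, ets = ets, kind = kind,
                 control = control, manipulated = manipulated),
            class = "cellline_model")
}

#' @export
print.cellline_model <- function(x, ...) {
  cat(sprintf("cell-line model '%s' (%s of %s): control '%s', %d manipulated population(s)\n",
              x$name, x$kind, x$ets, x$control$label, length(x$manipulated)))
  invisible(x)
}

model_sample_ids <- function(model) {
  c(model$control$sample_ids,
    unlist(lapply(model$manipulated, `[[`, "sample_ids")))
}
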