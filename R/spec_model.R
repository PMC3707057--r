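#' Define a cognitive function
#'
#' A cognitive function is either binary (implicit levels `low` < `high`) or
#' leveled, with an explicit totally ordered set of level labels given from
#' lowest to highest. Possessing a level of a leveled function implies
#' possessing every lower level, so the within-function hierarchy is
#' structural rather than data: hierarchy-violating profiles are
#' unrepresentable.
#'
#' @param name identifier, unique within a specification.
#' @param kind `"binary"` or `"leveled"`.
#' @param levels for leveled functions, character vector of level labels,
#'   lowest to highest. Ignored (set to `c("low", "high")`) for binary
#'   functions.
#' @return an object of class `cognitive_function`.
#' @seealso [incidence_spec()], [np_measure()]
#' @export
cognitive_function <- function(name, kind = c("binary", "leveled"),
                               levels = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    levels <- c("low", "high")
  } else if (is.null(levels)) {
    stop("leveled function '", name, "' needs explicit levels", call. = FALSE)
  }
  structure(list(name = as.character(name), kind = kind,
                 levels = as.character(levels)),
            class = "cognitive_function")
}

#' Define a neuropsychological measure
#'
#' A measure is associated with the set of (function, minimum level) pairs a
#' subject must possess to be expected to perform well on it (the "X" marks
#' of a Q-matrix-style incidence table). When an incidence table marks a
#' leveled function at several levels for the same measure, the requirement
#' is the highest marked level; the lower marks are implied by the
#' within-function hierarchy.
#'
#' @param name identifier, unique within a specification.
#' @param requires named character vector mapping function names to the
#'   minimum required level label (for binary functions, `"high"`).
#' @param direction `"higher"` if larger raw scores indicate better
#'   performance (e.g. recall counts), `"lower"` if smaller raw scores do
#'   (e.g. completion times, error counts).
#' @return an object of class `np_measure`.
#' @export
np_measure <- function(name, requires, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  structure(list(name = as.character(name),
                 requires = requires, direction = direction),
            class = "np_measure")
}

#' Assemble an attribute-measure incidence specification
#'
#' Bundles cognitive functions and measures into the specification object
#' that drives model generation, response-distribution fitting and
#' classification. The constructor performs no validation beyond basic
#' shape; use [validate_spec()] for diagnostics or [load_spec()] for a
#' validating reader.
#'
#' @param functions list of [cognitive_function()] objects.
#' @param measures list of [np_measure()] objects.
#' @param name optional label for the specification.
#' @return an object of class `incidence_spec`.
#' @export
incidence_spec <- function(functions, measures, name = "spec") {
  fn <- stats::setNames(functions, vapply(functions, `[[`, "", "name"))
  ms <- stats::setNames(measures, vapply(measures, `[[`, "", "name"))
  structure(list(name = name, functions = fn, measures = ms),
            class = "incidence_spec")
}

#' @export
print.incidence_spec <- function(x, ...) {
  cat("Incidence specification '", x$name, "': ",
      length(x$functions), " functions, ", length(x$measures),
      " measures\n", sep = "")
  for (f in x$functions)
    cat("  function ", f$name, " [", f$kind, "]: ",
        paste(f$levels, collapse = " < "), "\n", sep = "")
  for (m in x$measures)
    cat("  measure ", m$name, " (", m$direction, "-is-better): requires ",
        paste(names(m$requires), m$requires, sep = ">=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Validate an incidence specification
#'
#' Checks every structural invariant of the specification and returns one
#' diagnostic message per violation, each naming the offending entity. An
#' empty character vector means the specification is valid. Unlike
#' [load_spec()], this never throws.
#'
#' @param spec an [incidence_spec()].
#' @return character vector of diagnostics (zero-length if valid).
#' @export
validate_spec <- function(spec) {
  out <- character()
  fnames <- vapply(spec$functions, `[[`, "", "name")
  mnames <- vapply(spec$measures, `[[`, "", "name")
  dup <- unique(fnames[duplicated(fnames)])
  if (length(dup))
    out <- c(out, paste0("duplicate function name: ", dup))
  dup <- unique(mnames[duplicated(mnames)])
  if (length(dup))
    out <- c(out, paste0("duplicate measure name: ", dup))
  clash <- intersect(fnames, mnames)
  if (length(clash))
    out <- c(out, paste0("name used for both a function and a measure: ",
                         clash))
  for (f in spec$functions) {
    if (length(f$levels) < 2)
      out <- c(out, paste0("function '", f$name,
                           "' has fewer than 2 levels"))
    if (anyDuplicated(f$levels))
      out <- c(out, paste0("function '", f$name,
                           "' has duplicated level labels"))
    if (f$kind == "binary" && !identical(f$levels, c("low", "high")))
      out <- c(out, paste0("binary function '", f$name,
                           "' must have levels low < high"))
  }
  for (m in spec$measures) {
    req <- m$requires
    if (length(req) == 0) {
      out <- c(out, paste0("measure '", m$name,
                           "' has an empty requirement set"))
      next
    }
    if (is.null(names(req)) || any(!nzchar(names(req))))
      out <- c(out, paste0("measure '", m$name,
                           "' has unnamed requirements"))
    for (fn in names(req)) {
      if (!fn %in% fnames) {
        out <- c(out, paste0("measure '", m$name,
                             "' requires unknown function '", fn, "'"))
      } else {
        lv <- spec$functions[[fn]]$levels
        if (!req[[fn]] %in% lv)
          out <- c(out, paste0("measure '", m$name, "' requires level '",
                               req[[fn]], "' not defined for function '",
                               fn, "'"))
        else if (req[[fn]] == lv[1L])
          out <- c(out, paste0("measure '", m$name, "' requires function '",
                               fn, "' at its lowest level (vacuous)"))
      }
    }
    if (anyDuplicated(names(req)))
      out <- c(out, paste0("measure '", m$name,
                           "' lists a function twice"))
  }
  out
}

#' Read an incidence specification from JSON
#'
#' Parses and validates the documented JSON format: an object with a
#' `functions` array (`name`, `kind`, optional `levels`) and a `measures`
#' array (`name`, `direction`, `requires` = array of
#' `{function, level}` pairs). The bundled `adni_table1.json` fixture is an
#' example; see [adni_table1_spec()].
#'
#' @param source path to a JSON file, or a JSON string.
#' @return a validated [incidence_spec()].
#' @export
load_spec <- function(source) {
  txt <- source
  if (length(source) == 1 && !grepl("[{\n]", source)) {
    if (!file.exists(source))
      stop("spec file not found: ", source, call. = FALSE)
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("spec parse failure: ", conditionMessage(e),
                         call. = FALSE))
  for (field in c("functions", "measures"))
    if (is.null(doc[[field]]))
      stop("spec format error: missing '", field, "' array", call. = FALSE)
  fns <- lapply(doc$functions, function(f) {
    if (is.null(f$name) || is.null(f$kind))
      stop("spec format error: function entry without name/kind",
           call. = FALSE)
    cognitive_function(f$name, f$kind, unlist(f$levels))
  })
  ms <- lapply(doc$measures, function(m) {
    if (is.null(m$name))
      stop("spec format error: measure entry without name", call. = FALSE)
    for (r in m$requires)
      if (is.null(r[["function"]]) || is.null(r$level))
        stop("spec format error: requirement of measure '", m$name,
             "' needs fields 'function' and 'level'", call. = FALSE)
    req <- stats::setNames(vapply(m$requires, `[[`, "", "level"),
                           vapply(m$requires, `[[`, "", "function"))
    np_measure(m$name, req,
               direction = if (is.null(m$direction)) "higher" else m$direction)
  })
  spec <- incidence_spec(fns, ms,
                         name = if (is.null(doc$name)) "spec" else doc$name)
  diag <- validate_spec(spec)
  if (length(diag))
    stop("spec validation error:\n  ", paste(diag, collapse = "\n  "),
         call. = FALSE)
  spec
}

#' Serialize an incidence specification to JSON
#'
#' Inverse of [load_spec()]: `load_spec(write_spec(spec))` round-trips.
#'
#' @param spec an [incidence_spec()].
#' @param path optional output file; when `NULL`, the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_spec <- function(spec, path = NULL) {
  doc <- list(
    name = spec$name,
    functions = lapply(unname(spec$functions), function(f) {
      out <- list(name = f$name, kind = f$kind)
      if (f$kind == "leveled") out$levels <- f$levels
      out
    }),
    measures = lapply(unname(spec$measures), function(m) {
      list(name = m$name,
           direction = m$direction,
           requires = lapply(names(m$requires), function(fn)
             list("function" = fn, level = unname(m$requires[[fn]]))))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' The bundled ADNI battery specification
#'
#' Loads the packaged incidence specification for the ten-measure ADNI
#' neuropsychological battery: episodic memory as a single leveled function
#' (levels 0-3) plus four binary functions (word fluency, selective
#' attention, cognitive flexibility, perceptual motor speed). Selective
#' attention is required by every measure.
#'
#' @return a validated [incidence_spec()] with 5 functions and 10 measures.
#' @export
adni_table1_spec <- function() {
  load_spec(system.file("extdata", "adni_table1.json", package = "cogposet",
                        mustWork = TRUE))
}

# level label -> 0-based index within its function; errors on unknown input
level_index <- function(spec, fn, level) {
  f <- spec$functions[[fn]]
  if (is.null(f)) stop("unknown function: ", fn, call. = FALSE)
  i <- match(level, f$levels)
  if (is.na(i)) stop("unknown level '", level, "' for function '", fn, "'",
                     call. = FALSE)
  i - 1L
}

#' Function and measure names of a specification
#'
#' @param spec an [incidence_spec()].
#' @return character vector of names, in declaration order.
#' @export
spec_function_names <- function(spec) names(spec$functions)

#' @rdname spec_function_names
#' @export
spec_measure_names <- function(spec) names(spec$measures)

# integer requirement matrix: measures x functions, entry = minimal 0-based
# level index required (0 = no requirement)
requirement_matrix <- function(spec) {
  fns <- spec_function_names(spec)
  ms <- spec_measure_names(spec)
  R <- matrix(0L, nrow = length(ms), ncol = length(fns),
              dimnames = list(ms, fns))
  for (m in spec$measures)
    for (fn in names(m$requires))
      R[m$name, fn] <- level_index(spec, fn, m$requires[[fn]])
  R
}
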