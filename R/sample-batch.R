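#' Labelled batch of samples
#'
#' A thin container for an `n x d` matrix of realisations of one of the
#' system's variables: hidden sources `s`, sensory inputs `x`, neural outputs
#' `u`, or reconstruction errors.  Rows are observations; columns are
#' dimensions of the labelled variable.
#'
#' @param values Numeric matrix (or vector, treated as one column) of finite
#'   values.
#' @param variable_label One of `"sources"`, `"inputs"`, `"outputs"`,
#'   `"errors"`.
#' @param seed Optional integer recording the seed the batch was drawn with.
#' @return An object of class `sample_batch`.
#' @export
sample_batch <- function(values,
                         variable_label = c("sources", "inputs", "outputs",
                                            "errors"),
                         seed = NULL) {
  variable_label <- match.arg(variable_label)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop_invalid("a sample batch needs at least one row")
  if (!all(is.finite(values)))
    stop_invalid("sample batch values must all be finite")
  structure(list(values = values, variable_label = variable_label,
                 seed = seed),
            class = "sample_batch")
}

#' @export
as.matrix.sample_batch <- function(x, ...) x$values

#' @export
dim.sample_batch <- function(x) dim(x$values)

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("<sample_batch> %d x %d (%s)%s\n", nrow(x$values),
              ncol(x$values), x$variable_label,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# Accept either a sample_batch or a bare matrix; optionally check width.
batch_values <- function(batch, width = NULL, what = "batch") {
  v <- if (inherits(batch, "sample_batch")) batch$values else as.matrix(batch)
  if (!is.null(width) && ncol(v) != width)
    stop_invalid(sprintf("%s has width %d, expected %d", what, ncol(v), width))
  v
}
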