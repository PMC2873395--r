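# Internal helpers shared across modules.

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return The geometric mean of `x`.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0, na.rm = TRUE)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a configuration-style error naming the offending field.
.check <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

# Resolve a sample sheet (data.frame with sample_id, group) or a named
# character vector into a named group vector.
.group_vector <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "group") %in% names(samples)))
    stats::setNames(as.character(samples$group), samples$sample_id)
  } else if (!is.null(names(samples))) {
    stats::setNames(as.character(samples), names(samples))
  } else {
    stop("'samples' must be a sample sheet data.frame or a named group vector")
  }
}

# Pick case (e.g. tumour) and control levels for a two-group comparison.
# Default: the second factor level (alphabetical) is the case group, so that
# "normal" < "tumour" gives tumour - normal differences.
.two_groups <- function(groups, case_group = NULL) {
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("at least 2 groups are required")
  if (length(lev) > 2 && is.null(case_group)) {
    stop("more than 2 groups present; specify 'case_group'")
  }
  case <- case_group %||% lev[2]
  if (!case %in% lev) stop(sprintf("case group '%s' not present", case))
  control <- setdiff(lev, case)
  if (length(control) > 1) {
    stop("more than 2 groups present; subset the sample sheet first")
  }
  list(case = case, control = control)
}
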