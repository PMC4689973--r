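`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round a monetary figure to the nearest $100
#'
#' Reporting convention for ICERs: values are computed and stored unrounded,
#' and only the display layer rounds to the nearest hundred dollars.
#'
#' @param x Numeric vector of dollar amounts.
#' @return `x` rounded to the nearest 100.
#' @export
round_icer <- function(x) round(x / 100) * 100

#' Read a model parameter by path
#'
#' Parameters inside a [model configuration][load_config] are addressed by
#' dot-separated paths, e.g. `"strategies.denosumab.annual_drug_cost"` or
#' `"utilities.multiplier_year1.hip"`.  Purely numeric path components index
#' by position (e.g. `"persistence.3"`).
#'
#' @param config A model configuration.
#' @param path Dot-separated parameter path.
#' @return The value stored at `path`.
#' @seealso [param_set()]
#' @export
param_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    ok <- if (is.character(idx)) {
      !is.null(names(node)) && idx %in% names(node)
    } else {
      idx >= 1L && idx <= length(node)
    }
    if (!ok) {
      stop("unknown parameter path: ", path, " (failed at '", k, "')",
           call. = FALSE)
    }
    node <- node[[idx]]
  }
  node
}

#' Set a model parameter by path
#'
#' @inheritParams param_get
#' @param value Replacement value.
#' @return The modified configuration.  The path must already exist; setting
#'   an unknown path is an error so that typos in sensitivity-analysis specs
#'   fail loudly.
#' @export
param_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  assign_in <- function(node, keys) {
    k <- keys[1]
    idx <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    ok <- if (is.character(idx)) {
      !is.null(names(node)) && idx %in% names(node)
    } else {
      idx >= 1L && idx <= length(node)
    }
    if (!ok) {
      stop("unknown parameter path: ", path, " (failed at '", k, "')",
           call. = FALSE)
    }
    if (length(keys) == 1L) {
      node[[idx]] <- value
    } else {
      node[[idx]] <- assign_in(node[[idx]], keys[-1])
    }
    node
  }
  assign_in(config, keys)
}

# Validation helper: signal a configuration error naming the offending field.
config_error <- function(field, msg) {
  stop("invalid configuration: field '", field, "' ", msg, call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || is.na(x)) {
    config_error(field, "must be a single number")
  }
  if (x < lower || (open_lower && x == lower)) {
    config_error(field, paste0("must be ", if (open_lower) "> " else ">= ",
                               lower, " (got ", x, ")"))
  }
  if (x > upper || (open_upper && x == upper)) {
    config_error(field, paste0("must be ", if (open_upper) "< " else "<= ",
                               upper, " (got ", x, ")"))
  }
  invisible(x)
}
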