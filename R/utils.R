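# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded draws inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical residue key "chain|resno|insert"; insert "" for none.
residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  chain <- ifelse(is.na(chain), "", chain)
  paste(chain, resno, insert, sep = "|")
}

# Pairwise Euclidean distance matrix for an N x 3 coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One structured log line per pipeline stage, to stderr.
log_stage <- function(stage, ...) {
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(names(kv), vapply(kv, function(x) paste(x, collapse = ","),
                            character(1)),
          sep = "=", collapse = " ")
  } else {
    ""
  }
  message(sprintf("[gnmflux] stage=%s %s", stage, txt))
}
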