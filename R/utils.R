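#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed plus a stage name, so that a single integer pins
#' down the whole run while stages remain decoupled.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 131 + cc) %% 1000000007
  }
  as.integer((abs(as.numeric(master)) %% 2147483 * 977 + h) %% 2147483398 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x * x))

# row-wise Euclidean norms of a matrix
row_norms <- function(m) sqrt(rowSums(m * m))
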