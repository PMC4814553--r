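#' @keywords internal
"_PACKAGE"

#' @useDynLib bistabledcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm rgamma sd var cor
#'   pf t.test chisq.test fisher.test dgamma setNames uniroot convolve
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(msg) stop(msg, call. = FALSE)

#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic stage of the pipeline receives its own integer seed
#' derived deterministically from one master seed, so that a single
#' integer reproduces the whole analysis and subsets of it can be rerun
#' in isolation.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @param stream optional character tag so different stages draw
#'   non-overlapping seed sets from the same master.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n, stream = "") {
  offset <- if (nzchar(stream)) sum(utf8ToInt(stream)) else 0L
  withr::with_seed(as.integer((as.numeric(master) + 1000003 * offset) %% .Machine$integer.max),
                   sample.int(.Machine$integer.max - 1L, n))
}
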