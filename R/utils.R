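#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed; independent
#' stages (sequence generation, fold assignment, negative sampling, weight
#' initialization, ...) draw from substreams derived by stably hashing the
#' master seed together with a stage name, so that regenerating one stage
#' never perturbs another.
#'
#' @param master_seed integer master seed.
#' @param name character scalar naming the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(name), length(name) == 1L)
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% mod
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% mod
  as.integer(h %% (mod - 1) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Structured log line
#'
#' Emits `timestamp level module message` to the message stream when
#' `options(hetmda.verbose = TRUE)`; silent otherwise.
#'
#' @param module character module label.
#' @param fmt sprintf format plus arguments.
#' @param ... values interpolated into `fmt`.
#' @param level log level label.
#' @return invisibly, the formatted line.
#' @export
hetmda_log <- function(module, fmt, ..., level = "INFO") {
  line <- sprintf("%s %s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, module, sprintf(fmt, ...))
  if (isTRUE(getOption("hetmda.verbose", FALSE))) message(line)
  invisible(line)
}

# normalize an identifier: exact matching after lowercasing + trimming
norm_id <- function(x) tolower(trimws(x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

logistic <- function(x) stats::plogis(x)
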