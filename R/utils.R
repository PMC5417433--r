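#' @keywords internal
"_PACKAGE"

# Canonical colonization stages, in biological order.
STAGES <- c("bark", "phloem", "brood")

# Compounds quantified in phloem extracts. 4-allylanisole is a phenylpropanoid,
# not a monoterpene, and is excluded from monoterpene totals.
MONOTERPENES <- c("alpha-pinene", "beta-pinene", "3-carene", "myrcene",
                  "limonene", "beta-phellandrene", "camphene")
COMPOUNDS <- c(MONOTERPENES, "4-allylanisole")

#' Derive a named substream seed from a master seed
#'
#' Each stochastic module (simulation, Monte Carlo integration, permutation
#' test) consumes its own substream so that results for one module do not
#' depend on whether another module ran first. The derivation is a small
#' deterministic hash of the master seed and the stream name, kept within
#' 32-bit integer range.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"simulate"`, `"mc"`, `"perm"`.
#' @return an integer seed.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  # double arithmetic: exact below 2^53, result folded into 32-bit range
  as.integer(((abs(master) %% 2147483629) * 2654435 + h * 97 + 12345) %%
               2147483629)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}

logit <- function(p) log(p / (1 - p))

check_stage <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L || !(stage %in% STAGES)) {
    stop("`stage` must be one of: ", paste(STAGES, collapse = ", "),
         call. = FALSE)
  }
  stage
}
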