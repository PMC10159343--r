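#' Derive a stage seed from a global seed
#'
#' Deterministic, order-independent derivation of per-stage RNG seeds from a
#' single global seed: a 31-bit polynomial rolling hash of the stage name
#' folded into the seed. Documented so any pipeline stage can be reproduced
#' in isolation.
#'
#' @param global_seed integer global seed.
#' @param stage_name character scalar naming the stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, stage_name) {
  stopifnot(length(stage_name) == 1L, is.character(stage_name))
  m <- 2147483647 # 2^31 - 1, keeps every product below 2^53
  h <- as.numeric(global_seed) %% m
  for (ch in utf8ToInt(stage_name)) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 1)) + 1L
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stable content hash of a plain R config structure (md5 of canonical JSON)
digest_config <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}
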