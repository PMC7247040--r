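# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed derived from a master seed and stream ids.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  acc <- 0
  for (x in ids) acc <- (acc * 69069 + as.double(x) + 1) %% 2147483647
  as.integer(acc)
}

write_provenance <- function(path, info) {
  info$package <- "conparc"
  info$version <- as.character(utils::packageVersion("conparc"))
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(path, ".json"))
}
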