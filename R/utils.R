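# Run code with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL means: use (and advance) the current RNG stream.
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE, ...)
}

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "rleaderScreen", mustWork = TRUE)
  p
}
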