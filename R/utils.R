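# internal helpers

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# full-precision, locale-independent number formatting (round-trips doubles)
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable, locale-independent ordering of a list of atomic sort keys
orderBy <- function(...) order(..., method = "radix")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
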