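# internal helpers shared across modules

# locale-independent sort so canonical keys are stable across platforms
sort_c <- function(x) sort(x, method = "radix")

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ti <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

write_tsv_plain <- function(df, file) {
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
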