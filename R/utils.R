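# Internal helpers shared across stages.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Per-stage seeds derived from one master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order conditions canonically: baseline, fungus-only, bacterium-only, both.
condition_of <- function(fungus, bacterium) {
  ifelse(fungus & bacterium, "both",
         ifelse(fungus, "fungus", ifelse(bacterium, "bacterium", "baseline")))
}

condition_levels <- function() c("baseline", "fungus", "bacterium", "both")

check_design <- function(design) {
  need <- c("sample_id", "fungus", "bacterium", "replicate")
  if (!all(need %in% names(design)))
    stopf("design must have columns %s", paste(need, collapse = ", "))
  design$fungus <- as.integer(design$fungus)
  design$bacterium <- as.integer(design$bacterium)
  if (!all(design$fungus %in% 0:1) || !all(design$bacterium %in% 0:1))
    stopf("design presence columns must be 0/1")
  design$condition <- condition_of(design$fungus == 1, design$bacterium == 1)
  tab <- table(factor(design$condition, levels = condition_levels()))
  if (any(tab == 0))
    stopf("all four community conditions must be present in the design")
  design
}
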