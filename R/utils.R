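## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stop with a classed condition so callers can distinguish configuration
## errors from data-validation errors programmatically.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("resilipig_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("resilipig_validation_error", "error")))
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_validation(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

## Canonical sort: by animal then age. Guarantees order-invariance of all
## downstream per-animal computations.
canonical_daily <- function(daily) {
  assert_cols(daily, c("animal_id", "age"), "daily records")
  daily <- daily[order(daily$animal_id, daily$age), , drop = FALSE]
  dup <- duplicated(daily[, c("animal_id", "age")])
  if (any(dup)) {
    stop_validation("duplicate (animal_id, age) daily records: e.g. ",
                    daily$animal_id[which(dup)[1]], " age ", daily$age[which(dup)[1]])
  }
  rownames(daily) <- NULL
  daily
}

## Deterministic per-animal RNG substream: a fixed linear-congruential hash of
## the root seed and a stable animal index. Keeps cohorts reproducible under
## reordering of animals and independent of how many animals precede one.
substream_seed <- function(root_seed, index) {
  s <- (as.double(root_seed) * 2654435761 + as.double(index) * 97531) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
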