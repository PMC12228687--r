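# Internal helpers shared across modules.

# stop with a classed condition so callers/tests can match on class
pm_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "petminer_error"))
}

pm_assert_file <- function(path) {
  if (!file.exists(path)) {
    pm_abort(paste0("input file not found: ", path), "petminer_missing_input")
  }
  invisible(path)
}

# Convert an embedding tibble (id + numeric columns) to a numeric matrix
# with ids as rownames. Validates finiteness and constant dimension.
embedding_matrix <- function(embeddings) {
  stopifnot(is.data.frame(embeddings))
  if (!"id" %in% names(embeddings)) {
    pm_abort("embedding table must have an 'id' column", "petminer_format_error")
  }
  if (anyDuplicated(embeddings$id)) {
    pm_abort("embedding ids must be unique", "petminer_format_error")
  }
  num <- embeddings[setdiff(names(embeddings), "id")]
  if (ncol(num) < 1L) {
    pm_abort("embedding table needs at least one numeric column",
             "petminer_format_error")
  }
  m <- as.matrix(num)
  if (!is.numeric(m) || !all(is.finite(m))) {
    pm_abort("embedding values must all be finite numerics",
             "petminer_format_error")
  }
  rownames(m) <- as.character(embeddings$id)
  m
}

# seeded RNG scoping: run code with a private RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
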