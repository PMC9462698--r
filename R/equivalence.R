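# Functional-equivalence machinery.  Mutations routinely produce programs
# that differ syntactically but compute the same function (dead instructions,
# renamed intermediates, reassociated sums).  Canonical dead-code elimination
# plus a quantized numeric fingerprint over random (feature, parameter)
# probes lets the evolution skip re-fitting such duplicates.  Equivalence
# under re-parameterization of the coefficient space is deliberately not
# detected: such forms are distinct points of the search space and are
# trained independently.

#' Remove instructions outside the backward dependency slice of F
#'
#' Backward liveness analysis from the readout variable: an instruction is
#' kept only if its output is live at that point.  The multiply-accumulate op
#' reads its own output, so a live accumulator keeps accumulating
#' instructions live.  Idempotent; the retained instructions compute exactly
#' the same readout as the input program.
#'
#' @param program A valid \code{xc_program}.
#' @return An \code{xc_program} with dead instructions removed.
#' @export
canonicalize <- function(program) {
  assert_valid_program(program)
  kinds <- ws_kinds(program)
  live <- "F"
  keep <- logical(length(program$instructions))
  for (i in rev(seq_along(program$instructions))) {
    ins <- program$instructions[[i]]
    if (ins$output %in% live) {
      keep[i] <- TRUE
      reads <- ins$inputs[kinds[ins$inputs] == "variable"]
      if (ins$op != "mac") live <- setdiff(live, ins$output)
      live <- union(live, reads)
    }
  }
  out <- program
  out$instructions <- program$instructions[keep]
  out
}

#' Probe specification for numeric fingerprints
#'
#' @param n_probe_points Number of random feature tuples.
#' @param n_parameter_draws Number of random parameter draws (standard normal
#'   truncated to the fitting box \code{[-10, 10]}).
#' @param quantization_digits Significant digits retained before hashing, so
#'   float-level differences between reassociated but equal expressions
#'   collapse to the same digest.
#' @param probe_seed RNG seed fixing the probe set; identical
#'   \code{(program, probe_spec)} pairs give identical digests across runs
#'   and platforms.
#' @return An \code{xc_probe_spec}.
#' @export
probe_spec <- function(n_probe_points = 64L, n_parameter_draws = 4L,
                       quantization_digits = 8L, probe_seed = 20220909L) {
  structure(list(n_probe_points = as.integer(n_probe_points),
                 n_parameter_draws = as.integer(n_parameter_draws),
                 quantization_digits = as.integer(quantization_digits),
                 probe_seed = as.integer(probe_seed)),
            class = "xc_probe_spec")
}

# Feature-specific probe distributions over realistic ranges.
sample_probe_feature <- function(name, n) {
  switch(name,
    x2 = 10^runif(n, -4, 4),
    u = runif(n),
    w = runif(n, -1, 1),
    x = sqrt(10^runif(n, -4, 4)),
    rho = 10^runif(n, -2, 1),
    s = runif(n, 0, 3),
    rs = runif(n, 0.1, 5),
    10^runif(n, -3, 3))
}

with_probe_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Numeric fingerprint of a program
#'
#' Canonicalizes, evaluates on a fixed pseudo-random probe set of feature
#' tuples under several random parameter draws, quantizes the outputs and
#' hashes them.  Programs equal as functions of features and parameters
#' jointly (up to floating-point reassociation) receive equal digests; an
#' invalid evaluation hashes a sentinel.
#'
#' @param program A valid \code{xc_program}.
#' @param spec An \code{\link{probe_spec}}.
#' @return List with \code{digest} (character) and \code{probe_spec}.
#' @export
fingerprint <- function(program, spec = probe_spec()) {
  canon <- canonicalize(program)
  plan <- compile_program(canon)
  q <- spec$quantization_digits
  rows <- with_probe_seed(spec$probe_seed, {
    feats <- lapply(setNames(plan$features, plan$features),
                    sample_probe_feature, n = spec$n_probe_points)
    lapply(seq_len(spec$n_parameter_draws), function(d) {
      pv <- pmin(pmax(rnorm(length(plan$parameters)), -10), 10)
      res <- exec_plan(plan, feats, as.list(setNames(pv, plan$parameters)),
                       n = spec$n_probe_points)
      if (!res$valid) "invalid" else sprintf("%.*e", q - 1L,
                                             signif(res$values, q))
    })
  })
  list(digest = rlang::hash(rows), probe_spec = spec)
}

#' Fingerprint of a whole functional
#'
#' Hash of the three per-channel digests, so any channel difference changes
#' the functional digest.
#'
#' @param functional An \code{xc_functional}.
#' @param spec An \code{\link{probe_spec}}.
#' @return Digest string.
#' @export
fingerprint_functional <- function(functional, spec = probe_spec()) {
  rlang::hash(lapply(functional$programs, function(p) fingerprint(p, spec)$digest))
}

#' Fitness cache keyed by fingerprint digest
#'
#' Stores the fitted parameters and train/validation errors of every
#' functional form seen, so that an equivalent form encountered again joins
#' the population without re-fitting.
#'
#' @return An environment-backed cache.
#' @export
new_fitness_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "xc_fitness_cache")
}

#' @rdname new_fitness_cache
#' @param cache A fitness cache.
#' @param digest Digest string.
#' @export
seen_before <- function(cache, digest) {
  rec <- if (exists(digest, envir = cache, inherits = FALSE))
    get(digest, envir = cache) else NULL
  list(hit = !is.null(rec), record = rec)
}

#' @rdname new_fitness_cache
#' @param record List with \code{params}, \code{J_train}, \code{J_val},
#'   \code{expression}.
#' @export
cache_store <- function(cache, digest, record) {
  assign(digest, record, envir = cache)
  invisible(cache)
}

cache_size <- function(cache) length(ls(envir = cache))

#' Persist / restore a fitness cache as JSON lines
#'
#' @param cache A fitness cache.
#' @param path File path (one JSON object per line).
#' @export
cache_save <- function(cache, path) {
  keys <- ls(envir = cache)
  lines <- vapply(keys, function(k) {
    rec <- get(k, envir = cache)
    rec$params <- as.list(rec$params)  # keep parameter names in JSON
    jsonlite::toJSON(c(list(digest = k), rec), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cache_save
#' @export
cache_load <- function(path) {
  cache <- new_fitness_cache()
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(line)) next
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    digest <- rec$digest
    rec$digest <- NULL
    rec$params <- unlist(rec$params)
    cache_store(cache, digest, rec)
  }
  cache
}
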