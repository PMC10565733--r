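#' Specification for a synthetic two-structure chunk data set
#'
#' Describes a labelled synthetic experiment: two latent polymorph structures
#' whose chunk observations have controlled within-structure and
#' between-structure intensity correlation, with per-chunk completeness
#' emulating angular chunks of helical data. The defaults emulate the
#' reference chunked trypsin experiment: ~40% per-chunk completeness, 48
#' chunks per structure, within-structure CC ~0.97 and between-structure CC
#' ~0.96. `n_unique` defaults to 50 000 unique reflections; tests and
#' examples scale it down since the CC statistics depend only on the overlap
#' size `completeness^2 * n_unique`.
#'
#' @param n_unique Unique reflections in the full model (default 50 000).
#' @param completeness Fraction of `n_unique` observed per chunk, in (0, 1]
#'   (default 0.4).
#' @param rho_within Target observed CC between two chunks of the same
#'   structure (default 0.97).
#' @param rho_between Target observed CC between chunks of different
#'   structures (default 0.96); must not exceed `rho_within`.
#' @param n_chunks_per_group Chunks per structure (default 48).
#' @param cell Nominal [unit_cell()] (default an orthorhombic trypsin-like
#'   cell).
#' @param cell_jitter_percent Gaussian jitter applied to each axis length per
#'   chunk, as percent of its value (default 0.05).
#' @param tip_noise_multiplier Optional noise multiplier applied to the last
#'   chunk of each group, emulating weak crystal-tip chunks (default 1 =
#'   off).
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_unique = 50000, completeness = 0.4,
                       rho_within = 0.97, rho_between = 0.96,
                       n_chunks_per_group = 48,
                       cell = unit_cell(54.9, 58.6, 67.2),
                       cell_jitter_percent = 0.05,
                       tip_noise_multiplier = 1,
                       seed = 1) {
  if (!(rho_between <= rho_within && rho_within <= 1 && rho_between > 0)) {
    abort_config("need 0 < rho_between <= rho_within <= 1")
  }
  if (completeness <= 0 || completeness > 1) {
    abort_config("completeness must lie in (0, 1]")
  }
  if (completeness * n_unique < 10) {
    abort_config("completeness * n_unique must be at least 10")
  }
  if (n_chunks_per_group < 2) abort_config("need at least 2 chunks per group")
  if (!is_unit_cell(cell)) abort_config("`cell` must be a unit_cell")
  structure(
    list(n_unique = n_unique, completeness = completeness,
         rho_within = rho_within, rho_between = rho_between,
         n_chunks_per_group = n_chunks_per_group, cell = cell,
         cell_jitter_percent = cell_jitter_percent,
         tip_noise_multiplier = tip_noise_multiplier, seed = seed),
    class = "synth_spec"
  )
}

# Deterministic bank of n_unique distinct Miller indices: layers of an
# expanding hkl box, restricted to Friedel-unique canonical triples (each
# index equals its own map_to_asu image under the identity group), so
# within-chunk merging never collapses two bank entries. Memoised.
index_bank <- local({
  cache <- list()
  function(n_unique) {
    key <- as.character(n_unique)
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- ceiling((2 * n_unique)^(1 / 3)) + 2
    g <- expand.grid(h = -m:m, k = -m:m, l = -m:m)
    canonical <- g$h > 0 |
      (g$h == 0 & g$k > 0) |
      (g$h == 0 & g$k == 0 & g$l > 0)
    g <- g[canonical, ]
    g <- g[order(abs(g$h) + abs(g$k) + abs(g$l), g$h, g$k, g$l), ]
    if (nrow(g) < n_unique) abort_config("index bank too small")
    out <- as.matrix(g[seq_len(n_unique), ])
    rownames(out) <- NULL
    cache[[key]] <<- out
    out
  }
})

#' Generate the two latent structure intensity vectors
#'
#' Structure A intensities are Wilson-like, `I_A ~ Exponential(1)` per
#' reflection. Structure B is the convex mixture
#' `I_B = (a * I_A + I') / (a + 1)` with `I'` an independent Exponential(1)
#' draw, which has `cor(I_A, I_B) = a / sqrt(a^2 + 1)` exactly. The mixing
#' weight is chosen in closed form so that the observed between-chunk CC,
#' after per-chunk noise calibrated to `rho_within`, equals `rho_between`:
#' the noise attenuates any latent correlation by a factor `rho_within`, so
#' the latent target is `rho_between / rho_within`. When
#' `rho_between == rho_within`, B is an exact copy of A.
#'
#' @param spec A [synth_spec()].
#' @return List with `I_a`, `I_b` (length `n_unique`), the latent
#'   correlation `rho_latent` and mixing weight `a` (Inf for the copy
#'   limit). Uses the current RNG state; seed via `set.seed()` or
#'   [generate_dataset()].
#' @export
generate_structures <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort_config("`spec` must be a synth_spec")
  I_a <- stats::rexp(spec$n_unique)
  rho_latent <- spec$rho_between / spec$rho_within
  if (rho_latent >= 1) {
    return(list(I_a = I_a, I_b = I_a, rho_latent = 1, a = Inf))
  }
  a <- rho_latent / sqrt(1 - rho_latent^2)
  I_b <- (a * I_a + stats::rexp(spec$n_unique)) / (a + 1)
  list(I_a = I_a, I_b = I_b, rho_latent = rho_latent, a = a)
}

#' Observe one noisy, incomplete chunk of a latent structure
#'
#' Samples a uniform-random subset of `completeness * n_unique` reflection
#' indices and adds independent Gaussian noise with
#' `sd = sqrt(var(I) * (1 - rho_within) / rho_within)`, so that two chunks of
#' the same structure have expected observed CC `rho_within` (signal variance
#' over total variance). The chunk's cell is the spec cell with Gaussian
#' jitter on each axis length.
#'
#' @param structure_I Latent intensity vector from [generate_structures()].
#' @param spec A [synth_spec()].
#' @param chunk_index 1-based chunk number within its crystal (sets the
#'   nominal 30-degree rotation range).
#' @param chunk_id,crystal_id,label Identity metadata.
#' @param noise_multiplier Extra factor on the noise sd (crystal-tip
#'   emulation).
#' @return A [reflection_chunk()]. Uses the current RNG state.
#' @export
observe_chunk <- function(structure_I, spec, chunk_index = 1,
                          chunk_id = sprintf("chunk%02d", chunk_index),
                          crystal_id = chunk_id, label = NULL,
                          noise_multiplier = 1) {
  if (!inherits(spec, "synth_spec")) abort_config("`spec` must be a synth_spec")
  n_obs <- round(spec$completeness * spec$n_unique)
  if (n_obs < 10) abort_config("completeness * n_unique must be at least 10")
  idx <- sort(sample.int(spec$n_unique, n_obs))
  sigma_n <- sqrt(stats::var(structure_I) *
                    (1 - spec$rho_within) / spec$rho_within) * noise_multiplier
  hkl <- index_bank(spec$n_unique)[idx, , drop = FALSE]
  jit <- 1 + rnorm(3, 0, spec$cell_jitter_percent / 100)
  cell <- unit_cell(spec$cell$a * jit[1], spec$cell$b * jit[2],
                    spec$cell$c * jit[3],
                    spec$cell$alpha, spec$cell$beta, spec$cell$gamma)
  reflection_chunk(
    tibble(h = hkl[, "h"], k = hkl[, "k"], l = hkl[, "l"],
           intensity = structure_I[idx] + rnorm(n_obs, 0, sigma_n),
           sigma = rep(max(sigma_n, .Machine$double.eps), n_obs)),
    chunk_id = chunk_id, crystal_id = crystal_id, cell = cell,
    rotation_start_deg = (chunk_index - 1) * 30,
    rotation_end_deg = chunk_index * 30,
    label = label
  )
}

#' Generate a complete labelled synthetic data set
#'
#' Builds both latent structures and emits `n_chunks_per_group` observed
#' chunks per structure, labelled `"A"` and `"B"`. Fully deterministic under
#' the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_dataset`: list with `chunks` (a
#'   [chunk_collection()]), `labels` (tibble `chunk_id`, `group`) and
#'   `structures` (the latent vectors).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort_config("`spec` must be a synth_spec")
  set.seed(spec$seed)
  structures <- generate_structures(spec)
  per_group <- spec$n_chunks_per_group
  mk <- function(group, I) {
    purrr::map(seq_len(per_group), function(i) {
      observe_chunk(
        I, spec, chunk_index = i,
        chunk_id = sprintf("%s%02d", group, i),
        crystal_id = sprintf("%s_xtal%d", group, (i - 1) %/% 12 + 1),
        label = group,
        noise_multiplier = if (i == per_group) spec$tip_noise_multiplier else 1
      )
    })
  }
  chunks <- chunk_collection(c(mk("A", structures$I_a), mk("B", structures$I_b)))
  labels <- tibble(
    chunk_id = chunk_ids(chunks),
    group = vapply(chunks$chunks, function(ch) ch$label, character(1))
  )
  structure(
    list(chunks = chunks, labels = labels, structures = structures,
         spec = spec),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d chunks (%d per group), completeness %.2g, rho_w=%.3g rho_b=%.3g\n",
              length(x$chunks), x$spec$n_chunks_per_group,
              x$spec$completeness, x$spec$rho_within, x$spec$rho_between))
  invisible(x)
}

#' Write a synthetic data set to chunk files
#'
#' Emits one tabular chunk file per chunk plus a `labels.tsv` sidecar
#' (`chunk_id`, `group`).
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written chunk files, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(dataset$chunks$chunks, function(ch) {
    p <- file.path(dir, paste0(ch$chunk_id, ".tsv"))
    write_chunk_table(ch, p)
    p
  }, character(1))
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tibble(chunk_id = chunk_ids(dataset$chunks), path = paths))
}
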