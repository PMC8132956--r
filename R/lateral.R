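#' 1:1 ortholog maps and lateral inference through an anchor species
#'
#' Consensus calls only relate the anchor species (S. purpuratus in the
#' Echinobase deployment) to one other species. Orthologs between two
#' non-anchor species X and Y are obtained by composing the anchor-X and
#' anchor-Y maps: `(x, y)` is inferred whenever some anchor gene is mapped to
#' both `x` and `y`. Composing two partial bijections yields a partial
#' bijection, so the 1:1 guarantee is preserved.
#'
#' @param pairs Data frame with integer columns `gene_a`, `gene_b`
#'   (`gene_a` belongs to `species_pair[1]`).
#' @param species_pair Ordered pair of species tags.
#' @param provenance `"consensus"` (direct calls) or `"inferred"` (composed).
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs, species_pair, provenance = c("consensus", "inferred")) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs <- pairs[, c("gene_a", "gene_b"), drop = FALSE]
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    .data_error("ortholog_map is not a partial bijection: duplicated gene on one side")
  }
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(species_pair = species_pair, pairs = pairs,
                 provenance = provenance),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("<ortholog_map>", paste(x$species_pair, collapse = " vs "), "-",
      nrow(x$pairs), "pairs (", x$provenance, ")\n")
  invisible(x)
}

#' @rdname ortholog_map
#' @param calls A `consensus_calls` object (anchor species first in its pair).
#' @export
as_ortholog_map <- function(calls) {
  stopifnot(inherits(calls, "consensus_calls"))
  ortholog_map(data.frame(gene_a = calls$gene_a, gene_b = calls$gene_b),
               attr(calls, "species_pair"), provenance = "consensus")
}

#' Laterally infer orthologs between two non-anchor species
#'
#' Composes an anchor-to-X map with an anchor-to-Y map: a pair `(x, y)` is
#' included iff some anchor gene `s` has `(s, x)` in `map_xa` and `(s, y)` in
#' `map_ya`. Both maps must share the anchor species (their first species
#' tag). By default only direct consensus maps may be composed; composing an
#' already-inferred map (a transitive chain) requires `allow_inferred = TRUE`.
#'
#' @param map_xa,map_ya [ortholog_map()]s with the anchor species first.
#' @param allow_inferred Permit inputs with `provenance = "inferred"`.
#' @return An `ortholog_map` X-to-Y with `provenance = "inferred"`; its size
#'   never exceeds the smaller input. Supports are not propagated.
#' @export
infer_lateral <- function(map_xa, map_ya, allow_inferred = FALSE) {
  stopifnot(inherits(map_xa, "ortholog_map"), inherits(map_ya, "ortholog_map"))
  if (!identical(map_xa$species_pair[1L], map_ya$species_pair[1L])) {
    .data_error("anchor species mismatch: '", map_xa$species_pair[1L],
                "' vs '", map_ya$species_pair[1L], "'")
  }
  if (!allow_inferred &&
      (map_xa$provenance != "consensus" || map_ya$provenance != "consensus")) {
    .data_error("refusing to compose an inferred map; set allow_inferred = TRUE")
  }
  hit <- match(map_xa$pairs$gene_a, map_ya$pairs$gene_a)
  sel <- !is.na(hit)
  ortholog_map(
    data.frame(gene_a = map_xa$pairs$gene_b[sel],
               gene_b = map_ya$pairs$gene_b[hit[sel]]),
    c(map_xa$species_pair[2L], map_ya$species_pair[2L]),
    provenance = "inferred")
}

#' Write an ortholog map as TSV
#'
#' Same schema as [write_consensus_tsv()] plus a `provenance` column; for
#' inferred maps `n_support` and `supporting_tools` are empty (supports are
#' not carried through composition).
#'
#' @param map An `ortholog_map`.
#' @param path Optional output path.
#' @return The lines, invisibly.
#' @export
write_ortholog_map_tsv <- function(map, path = NULL) {
  stopifnot(inherits(map, "ortholog_map"))
  sp <- map$species_pair
  rows <- if (nrow(map$pairs)) {
    paste(sp[1L], map$pairs$gene_a, sp[2L], map$pairs$gene_b, "", "",
          map$provenance, sep = "\t")
  }
  .emit_lines(c("species_a\tentrez_a\tspecies_b\tentrez_b\tn_support\tsupporting_tools\tprovenance",
                rows), path)
}
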