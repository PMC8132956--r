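#' Consensus configuration
#'
#' Holds the k-of-n voting threshold plus the recorded upstream tool
#' parameters. The default `k = 3` follows the Alliance of Genome Resources
#' convention that a gene pair is orthologous when three or more independent
#' tools converge; it is configurable because only six tools are run here.
#' The e-value (1e-40) and FastOrtho inflation (1.5) under which the tools
#' were run are carried as metadata only — the tools themselves are never
#' executed by this package.
#'
#' @param k Minimum number of supporting tools for a call (default 3).
#' @param tools_required Tool tags expected in a full suite.
#' @param evalue_recorded,inflation_recorded Recorded upstream parameters.
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(k = 3L, tools_required = .tool_tags,
                             evalue_recorded = 1e-40, inflation_recorded = 1.5) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(tools_required)) {
    .config_error("k must satisfy 1 <= k <= ", length(tools_required),
                  " (number of tools); got ", k)
  }
  structure(list(k = k, tools_required = tools_required,
                 evalue_recorded = evalue_recorded,
                 inflation_recorded = inflation_recorded),
            class = "consensus_config")
}

#' Tally exact-pair votes across normalized tool outputs
#'
#' A tool votes for the ortholog pair `(a, b)` if and only if its normalized
#' output contains a group whose member set is exactly
#' `{(species_a, a), (species_b, b)}` — one gene per species, both species
#' present. Larger groups (co-ortholog clusters) cast no 1:1 votes.
#'
#' @param outputs List of `normalized_output` objects sharing one species
#'   pair, at most one per tool.
#' @return A `vote_table`: data frame with columns `gene_a`, `gene_b` and a
#'   list column `tools`; attribute `species_pair`.
#' @export
vote_pairs <- function(outputs) {
  if (!length(outputs)) {
    return(structure(data.frame(gene_a = integer(), gene_b = integer(),
                                tools = I(list())),
                     species_pair = NULL, class = c("vote_table", "data.frame")))
  }
  pairs <- unique(lapply(outputs, `[[`, "species_pair"))
  if (length(pairs) != 1L) .data_error("vote_pairs: outputs mix species pairs")
  tools <- vapply(outputs, `[[`, character(1), "tool")
  if (anyDuplicated(tools)) {
    .data_error("vote_pairs: duplicate tool output for ", tools[duplicated(tools)][1L])
  }
  sp <- pairs[[1L]]
  key <- character(); ga <- integer(); gb <- integer(); tl <- character()
  for (o in outputs) {
    for (g in o$groups) {
      m <- g$members
      if (nrow(m) != 2L || !setequal(m$species, sp)) next
      a <- m$gene[m$species == sp[1L]]
      b <- m$gene[m$species == sp[2L]]
      key <- c(key, paste(a, b))
      ga <- c(ga, a); gb <- c(gb, b); tl <- c(tl, o$tool)
    }
  }
  u <- !duplicated(key)
  votes <- data.frame(gene_a = ga[u], gene_b = gb[u])
  votes$tools <- I(unname(split(tl, factor(key, levels = key[u]))))
  structure(votes, species_pair = sp, class = c("vote_table", "data.frame"))
}

#' Call 1:1 orthologs from the vote table
#'
#' Retains pairs supported by at least `cfg$k` tools, then enforces the 1:1
#' guarantee: within the result each gene appears on its side exactly once.
#' If a gene sits in several above-threshold pairs (tools disagreeing on the
#' partner), the pair with strictly more votes is kept; on a tie all pairs
#' involving that gene are dropped, and every dropped pair is counted as a
#' conflict.
#'
#' @param votes A `vote_table` from [vote_pairs()].
#' @param cfg A [consensus_config()].
#' @return A `consensus_calls` data frame, sorted by `(gene_a, gene_b)`, with
#'   columns `gene_a`, `gene_b`, `n_support`, `supporting_tools`
#'   (comma-joined, sorted); attributes `species_pair`, `k`, `n_conflicts`.
#' @export
call_consensus <- function(votes, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  n <- vapply(votes$tools, length, integer(1))
  keep <- votes[n >= cfg$k, , drop = FALSE]
  nk <- n[n >= cfg$k]
  survives <- rep(TRUE, nrow(keep))
  for (side in c("gene_a", "gene_b")) {
    for (g in unique(keep[[side]][duplicated(keep[[side]])])) {
      idx <- which(keep[[side]] == g)
      mx <- max(nk[idx])
      winners <- idx[nk[idx] == mx]
      if (length(winners) > 1L) survives[idx] <- FALSE       # tie: drop all
      else survives[setdiff(idx, winners)] <- FALSE
    }
  }
  n_conflicts <- sum(!survives)
  out <- data.frame(
    gene_a = keep$gene_a[survives],
    gene_b = keep$gene_b[survives],
    n_support = nk[survives],
    supporting_tools = vapply(keep$tools[survives],
                              function(t) paste(sort(t), collapse = ","),
                              character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, species_pair = attr(votes, "species_pair"), k = cfg$k,
            n_conflicts = n_conflicts,
            class = c("consensus_calls", "data.frame"))
}

#' @export
print.consensus_calls <- function(x, ...) {
  sp <- attr(x, "species_pair")
  cat("<consensus_calls>", if (!is.null(sp)) paste(sp, collapse = " vs "),
      "-", nrow(x), "1:1 calls at k >=", attr(x, "k"), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Run the full consensus pipeline for one species pair
#'
#' Parses each tool's raw output, normalizes it to gene level, tallies
#' exact-pair votes and calls the k-of-n consensus. At least `cfg$k` outputs
#' must be available, otherwise no pair could possibly reach the threshold.
#'
#' @param paths Named list/vector (tool tag -> file path) of raw tool
#'   outputs; alternatively a named list of already-parsed [tool_output()]s.
#' @param species_pair Ordered species pair (anchor first).
#' @param idmaps Named list of [idmap()]s, one per species.
#' @param cfg A [consensus_config()].
#' @param species_labels Optional per-tool named list of label-to-tag maps.
#' @param strict Passed to [to_gene_level()].
#' @return List with `calls` (a `consensus_calls`), `normalized` (the
#'   per-tool `normalized_output`s) and `audit` (per-tool normalization
#'   audits plus `n_calls` and `n_conflicts`).
#' @export
consensus_pipeline <- function(paths, species_pair, idmaps,
                               cfg = consensus_config(),
                               species_labels = NULL, strict = FALSE) {
  if (length(paths) < cfg$k) {
    .config_error("only ", length(paths), " tool output(s) supplied; k = ",
                  cfg$k, " can never be reached")
  }
  outputs <- lapply(names(paths), function(tool) {
    x <- paths[[tool]]
    if (!inherits(x, "tool_output")) {
      x <- read_tool_output(tool, x, species_pair, species_labels[[tool]])
    }
    to_gene_level(x, idmaps, strict = strict)
  })
  votes <- vote_pairs(outputs)
  calls <- call_consensus(votes, cfg)
  audits <- lapply(outputs, `[[`, "audit")
  names(audits) <- vapply(outputs, `[[`, character(1), "tool")
  names(outputs) <- names(audits)
  list(calls = calls, normalized = outputs,
       audit = list(per_tool = audits, n_calls = nrow(calls),
                    n_conflicts = attr(calls, "n_conflicts")))
}

#' Write / read consensus calls as TSV
#'
#' Columns `species_a`, `entrez_a`, `species_b`, `entrez_b`, `n_support`,
#' `supporting_tools` (comma-joined, sorted) with header; rows sorted by
#' `(entrez_a, entrez_b)` so reruns are byte-identical.
#'
#' @param calls A `consensus_calls`.
#' @param path Optional output path.
#' @return `write_consensus_tsv()` the lines invisibly; `read_consensus_tsv()`
#'   a `consensus_calls` (without `k` attribute).
#' @export
write_consensus_tsv <- function(calls, path = NULL) {
  sp <- attr(calls, "species_pair")
  if (is.null(sp)) sp <- c("a", "b")
  rows <- if (nrow(calls)) {
    paste(sp[1L], calls$gene_a, sp[2L], calls$gene_b, calls$n_support,
          calls$supporting_tools, sep = "\t")
  }
  .emit_lines(c("species_a\tentrez_a\tspecies_b\tentrez_b\tn_support\tsupporting_tools",
                rows), path)
}

#' @rdname write_consensus_tsv
#' @param x Input path, connection or lines.
#' @export
read_consensus_tsv <- function(x) {
  lines <- .as_lines(x)
  if (!length(lines) || !startsWith(lines[1L], "species_a\tentrez_a")) {
    .data_error("not a consensus TSV (header missing)")
  }
  lines <- lines[-1L][nzchar(lines[-1L])]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 6L)) .data_error("consensus TSV row with wrong column count")
  sp <- if (length(f)) c(f[[1L]][1L], f[[1L]][3L]) else NULL
  out <- data.frame(
    gene_a = as.integer(vapply(f, `[[`, character(1), 2L)),
    gene_b = as.integer(vapply(f, `[[`, character(1), 4L)),
    n_support = as.integer(vapply(f, `[[`, character(1), 5L)),
    supporting_tools = vapply(f, `[[`, character(1), 6L),
    stringsAsFactors = FALSE)
  structure(out, species_pair = sp, class = c("consensus_calls", "data.frame"))
}
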