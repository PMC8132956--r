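# Internal helpers shared across modules.

# RefSeq protein accession: two letters, underscore, digits, optional ".version".
.refseq_re <- "[A-Za-z]{2}_[0-9]+(?:\\.[0-9]+)?"

.is_refseq <- function(x) grepl(paste0("^", .refseq_re, "$"), x)

.strip_version <- function(x) sub("\\.[0-9]+$", "", x)

.accession_version <- function(x) {
  v <- rep(NA_integer_, length(x))
  has <- grepl("\\.[0-9]+$", x)
  v[has] <- as.integer(sub("^.*\\.([0-9]+)$", "\\1", x[has]))
  v
}

# Coerce a text input to lines: a connection is read; a length-1 character
# naming an existing file is read (gzip detected by file()); anything else is
# taken to already be a vector of lines.
.as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  as.character(x)
}

# Writers return the rendered lines invisibly; when `path` is given they also
# write them (so in-memory round-trips need no temp files).
.emit_lines <- function(lines, path = NULL) {
  if (!is.null(path)) {
    if (inherits(path, "connection")) writeLines(lines, path) else writeLines(lines, con = path)
  }
  invisible(lines)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Condition helpers: data errors (exit 1 at the CLI) vs config errors (exit 2).
.data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("orthovote_data_error", "orthovote_error")))
}

.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("orthovote_config_error", "orthovote_error")))
}

.tool_tags <- c("orthofinder", "proteinortho", "inparanoid", "oma",
                "swiftortho", "fastortho")
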