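#' Construct a discrete character matrix
#'
#' The container for morphological character data: an integer matrix of
#' states (rows = taxa, columns = characters) with `NA` for missing cells
#' and a per-character state count `k`.
#'
#' @param states integer matrix; rownames are taxon labels, `NA` = missing.
#' @param n_states integer vector, one `k >= 1` per character (recycled from
#'   a scalar).  Every observed state of character `j` must lie in
#'   `0..n_states[j]-1`.
#' @param char_ids stable character identifiers surviving filtering
#'   (default `"c1"`, `"c2"`, ...).
#' @return object of class `char_matrix` with elements `states`, `n_states`,
#'   `taxa`, `char_ids`.
#' @export
char_matrix <- function(states, n_states = 2L, char_ids = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  taxa <- rownames(states)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(states)))
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (nrow(states) < 1L) stop("need at least one taxon")
  n_states <- as.integer(rep_len(n_states, ncol(states)))
  if (ncol(states) > 0L && any(n_states < 1L)) stop("n_states must be >= 1")
  if (is.null(char_ids))
    char_ids <- paste0("c", seq_len(ncol(states)), recycle0 = TRUE)
  if (length(char_ids) != ncol(states)) stop("char_ids length mismatch")
  for (j in seq_len(ncol(states))) {
    obs <- states[, j][!is.na(states[, j])]
    if (any(obs < 0L | obs >= n_states[j]))
      stop(sprintf("character %s: observed state outside 0..%d",
                   char_ids[j], n_states[j] - 1L))
  }
  rownames(states) <- taxa
  colnames(states) <- char_ids
  structure(list(states = states, n_states = n_states,
                 taxa = taxa, char_ids = char_ids),
            class = "char_matrix")
}

subset_chars <- function(x, keep) {
  char_matrix(x$states[, keep, drop = FALSE],
              n_states = x$n_states[keep],
              char_ids = x$char_ids[keep])
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters (k: %s), %d missing cells\n",
              nrow(x$states), ncol(x$states),
              paste(unique(x$n_states), collapse = "/"),
              sum(is.na(x$states))))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

#' Read a NEXUS discrete character matrix
#'
#' Parses a DATA or CHARACTERS block (DIMENSIONS, FORMAT with SYMBOLS and
#' MISSING, MATRIX).  State symbols map to integers by their position in
#' SYMBOLS; the missing symbol (default `?`) and gaps (`-`) become `NA`.
#' Polymorphic or ambiguous codings such as `(01)` or `{01}` are read but
#' conservatively treated as missing.
#'
#' @param path path to a NEXUS file.
#' @param k_from `"symbols"` (default): every character gets
#'   `k = nchar(SYMBOLS)`; `"observed"`: per-character `k` = observed
#'   maximum state + 1 (at least 2).
#' @return a [char_matrix].
#' @export
read_nexus_matrix <- function(path, k_from = c("symbols", "observed")) {
  k_from <- match.arg(k_from)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- strip_nexus_comments(paste(readLines(path, warn = FALSE), collapse = "\n"))
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) stop("not a NEXUS file: ", path)
  block <- regmatches(txt, regexpr(
    "(?is)begin\\s+(data|characters)\\s*;.*?end\\s*;", txt, perl = TRUE))
  if (length(block) == 0L) stop("no DATA/CHARACTERS block in ", path)
  get_num <- function(key) {
    m <- regmatches(block, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"),
                                   block, perl = TRUE))
    if (length(m) == 0L) stop("missing ", key, " in DIMENSIONS")
    as.integer(sub(".*=\\s*", "", m))
  }
  ntax <- get_num("ntax")
  nchar_ <- get_num("nchar")
  sym_m <- regmatches(block, regexpr('(?i)symbols\\s*=\\s*"[^"]*"', block, perl = TRUE))
  symbols <- if (length(sym_m)) {
    gsub(" ", "", sub('.*"([^"]*)".*', "\\1", sym_m))
  } else "01"
  mis_m <- regmatches(block, regexpr("(?i)missing\\s*=\\s*\\S", block, perl = TRUE))
  missing_sym <- if (length(mis_m)) substring(mis_m, nchar(mis_m)) else "?"
  mat_m <- regmatches(block, regexpr("(?is)matrix(.*?);", block, perl = TRUE))
  if (length(mat_m) == 0L) stop("no MATRIX statement in ", path)
  body <- sub("(?is)^matrix", "", sub(";$", "", mat_m), perl = TRUE)
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[nzchar(rows)]
  if (length(rows) != ntax)
    stop(sprintf("matrix has %d rows but NTAX=%d (last row read: '%s')",
                 length(rows), ntax, if (length(rows)) rows[length(rows)] else ""))
  taxa <- character(ntax)
  states <- matrix(NA_integer_, ntax, nchar_)
  sym_vec <- strsplit(symbols, "")[[1]]
  for (i in seq_len(ntax)) {
    parts <- regmatches(rows[i], regexec("^(\\S+)\\s*(.*)$", rows[i]))[[1]]
    if (length(parts) != 3L || (nchar_ > 0L && !nzchar(parts[3])))
      stop("cannot parse matrix row: '", rows[i], "'")
    taxa[i] <- gsub("^'|'$", "", parts[2])
    cells <- gsub("\\s", "", parts[3])
    # tokenize: single symbols, or (..)/{..} polymorphism groups
    toks <- regmatches(cells, gregexpr("\\([^)]*\\)|\\{[^}]*\\}|.", cells))[[1]]
    if (length(toks) != nchar_)
      stop(sprintf("row '%s' has %d characters but NCHAR=%d",
                   taxa[i], length(toks), nchar_))
    for (j in seq_len(nchar_)) {
      tok <- toks[j]
      if (tok == missing_sym || tok == "-" || nchar(tok) > 1L) next  # MISSING
      pos <- match(tok, sym_vec)
      if (is.na(pos))
        stop(sprintf("undeclared symbol '%s' at taxon '%s', character %d",
                     tok, taxa[i], j))
      states[i, j] <- pos - 1L
    }
  }
  rownames(states) <- taxa
  n_states <- if (k_from == "symbols") length(sym_vec) else {
    apply(states, 2, function(col) max(2L, max(col, na.rm = TRUE) + 1L))
  }
  char_matrix(states, n_states = n_states)
}

#' Write a character matrix as NEXUS
#'
#' @param x a [char_matrix].
#' @param path output file path.
#' @return `path`, invisibly.  `read_nexus_matrix(write_nexus_matrix(x))`
#'   round-trips states, taxa and state counts.
#' @export
write_nexus_matrix <- function(x, path) {
  stopifnot(inherits(x, "char_matrix"))
  k <- max(x$n_states, 2L)
  symbols <- paste(c(0:9, LETTERS)[seq_len(k)], collapse = "")
  sym_vec <- strsplit(symbols, "")[[1]]
  rows <- vapply(seq_len(nrow(x$states)), function(i) {
    cells <- vapply(x$states[i, ], function(s)
      if (is.na(s)) "?" else sym_vec[s + 1L], character(1))
    paste0(x$taxa[i], "  ", paste(cells, collapse = ""))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x$states), ncol(x$states)),
    sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;', symbols),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"), con)
  invisible(path)
}

#' Read a tip-date table
#'
#' CSV with columns `taxon` and `age` (Ma before the reference time; point
#' values).
#'
#' @param path CSV path.
#' @return named numeric vector of ages.
#' @export
read_tip_dates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "age") %in% names(df)))
    stop("tip-date table needs columns 'taxon' and 'age'")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon in tip-date table")
  if (any(df$age < 0)) stop("tip ages must be >= 0")
  stats::setNames(as.numeric(df$age), df$taxon)
}

#' Write a tip-date table
#' @param ages named numeric vector of tip ages (Ma).
#' @param path CSV path.
#' @export
write_tip_dates <- function(ages, path) {
  utils::write.csv(data.frame(taxon = names(ages), age = as.numeric(ages)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
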