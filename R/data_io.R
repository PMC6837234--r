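#' Canonical kin-type codes
#'
#' The ten consanguineal kin categories the package analyses, in genealogical
#' shorthand: each letter steps through the genealogy (F father, M mother,
#' B brother, Z sister, S son, D daughter), so e.g. `MZ` is mother's sister
#' and `MZD` mother's sister's daughter.
#'
#' @return Named character vector mapping kin-type code to an English gloss.
#' @export
#' @examples
#' kin_types()
kin_types <- function() {
  c(B = "brother", D = "daughter", F = "father", M = "mother",
    MB = "mother's brother", MZ = "mother's sister",
    MZD = "mother's sister's daughter", MZS = "mother's sister's son",
    S = "son", Z = "sister")
}

## Label reconciliation between word-list languages and tree tips:
## exact match after Unicode NFC normalization and case folding.
canon_label <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(as.character(x)))
}

#' Read a word-list table
#'
#' Reads a UTF-8 CSV with at least the columns `language`, `meaning`, `form`.
#' Optional columns: `transcription` (segmental string used instead of the
#' orthographic form when present) and `lexical_class` (`"kin"` or
#' `"swadesh"`); when `lexical_class` is absent it is inferred from the
#' meaning label (a kin-type code from [kin_types()] is `kin`, anything else
#' `swadesh`).
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with columns `language`, `meaning`, `form`,
#'   `transcription` (NA where absent) and `lexical_class`.
#' @export
read_wordlist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("language", "meaning", "form")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("word list ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) {
    df$transcription <- character(0)
    df$lexical_class <- character(0)
    return(df[c(need, "transcription", "lexical_class")])
  }
  if (is.null(df$transcription)) df$transcription <- NA_character_
  if (is.null(df$lexical_class))
    df$lexical_class <- ifelse(df$meaning %in% names(kin_types()),
                               "kin", "swadesh")
  bad <- which(is.na(df$form) | !nzchar(trimws(df$form)))
  if (length(bad))
    stop("empty form at data line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  bad <- which(!df$lexical_class %in% c("kin", "swadesh"))
  if (length(bad))
    stop("lexical_class must be 'kin' or 'swadesh'; offending data line(s) ",
         paste(bad + 1L, collapse = ", "))
  key <- paste(df$language, df$meaning, df$form, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (language, meaning, form) at data line(s) ",
         paste(dup + 1L, collapse = ", "), " of ", path)
  df[c(need, "transcription", "lexical_class")]
}

#' Read a sample of rooted dated phylogenies
#'
#' Trees must be rooted, with finite non-negative branch lengths in years.
#' NEXUS translate blocks are supported via [ape::read.nexus()].
#'
#' @param path Tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return A `tree_sample`: list with `trees` (a `multiPhylo`) and `taxa`
#'   (the shared label universe, the union of leaf labels).
#' @export
read_tree_sample <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- if (format == "newick") ape::read.tree(path) else
    ape::read.nexus(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!length(trees)) stop("no trees found in ", path)
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]], sprintf("tree %d", i))
  tree_sample(trees)
}

#' Bundle phylogenies into a tree sample
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @return A `tree_sample` object.
#' @export
tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(t) t)
  if (!length(trees)) stop("tree sample must be non-empty")
  lapply(seq_along(trees), function(i)
    validate_phylogeny(trees[[i]], sprintf("tree %d", i)))
  class(trees) <- "multiPhylo"
  structure(list(trees = trees,
                 taxa = sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "tree(s) over",
      length(x$taxa), "taxa\n")
  invisible(x)
}

validate_phylogeny <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) stop(what, " is not a phylo object")
  if (!ape::is.rooted(tree)) stop(what, " is not rooted")
  if (is.null(tree$edge.length)) stop(what, " has no branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop(what, " has non-finite branch lengths")
  if (any(tree$edge.length < 0)) stop(what, " has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop(what, " has duplicate leaf labels")
  invisible(tree)
}

#' Prune a phylogeny to a taxon subset
#'
#' Drops all leaves outside `taxa`, collapsing degree-2 nodes and summing
#' their branch lengths, so all path lengths among retained leaves are
#' preserved.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param taxa Character vector of leaf labels to keep (at least 2, all
#'   present in the tree).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa to prune to")
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Read a corpus frequency table
#'
#' CSV columns: `language`, `word`, `meaning`, `corpus_id`, `corpus_type`
#' (one of spoken/written/web), `count`, `corpus_size` (tokens).
#'
#' @param path CSV path.
#' @return Validated `data.frame` of corpus counts.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("language", "word", "meaning", "corpus_id", "corpus_type",
            "count", "corpus_size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("frequency table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$corpus_type %in% c("spoken", "written", "web"))
  if (length(bad))
    stop("corpus_type outside {spoken, written, web} at data line(s) ",
         paste(bad + 1L, collapse = ", "))
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("count must be a non-negative integer; data line(s) ",
         paste(bad + 1L, collapse = ", "))
  bad <- which(is.na(df$corpus_size) | df$corpus_size <= 0)
  if (length(bad))
    stop("corpus_size must be positive; data line(s) ",
         paste(bad + 1L, collapse = ", "))
  bad <- which(df$count > df$corpus_size)
  if (length(bad))
    stop("count exceeds corpus_size at data line(s) ",
         paste(bad + 1L, collapse = ", "))
  df[need]
}

#' Read an expert override table
#'
#' CSV columns: `meaning`, `language`, `form`, `class`. Each
#' (meaning, language, form) may appear at most once.
#'
#' @param path CSV path.
#' @return Validated `data.frame` of overrides.
#' @export
read_overrides <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("meaning", "language", "form", "class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("override table lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$meaning, df$language, df$form, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate override for one (meaning, language, form) at data line(s) ",
         paste(dup + 1L, collapse = ", "))
  df[need]
}

# ---- multistate characters -------------------------------------------------

#' Construct a multistate character
#'
#' A multistate character maps each taxon to a cognate-class state for one
#' meaning: a named integer vector of states `0..k-1` with `NA` for missing.
#'
#' @param states Integer states (0-based) or `NA`, named by taxon.
#' @param meaning Meaning label the character encodes.
#' @return A `multistate_character`.
#' @export
multistate_character <- function(states, meaning = NA_character_) {
  if (is.null(names(states)) || !all(nzchar(names(states))))
    stop("states must be named by taxon")
  if (anyDuplicated(names(states))) stop("duplicate taxon names")
  nm <- names(states)
  states <- as.integer(states)
  names(states) <- nm
  ok <- is.na(states) | states >= 0L
  if (!all(ok)) stop("states must be non-negative integers or NA")
  structure(states, meaning = as.character(meaning),
            class = "multistate_character")
}

#' @export
print.multistate_character <- function(x, ...) {
  k <- length(unique(x[!is.na(x)]))
  cat("Multistate character", if (!is.na(attr(x, "meaning")))
    paste0("'", attr(x, "meaning"), "'"), ":",
    length(x), "taxa,", k, "observed state(s),",
    sum(is.na(x)), "missing\n")
  invisible(x)
}

state_symbols <- function() c(0:9, LETTERS, letters)

#' Write multistate characters as a NEXUS standard-data matrix
#'
#' One column per character (meaning), one row per taxon; states use symbols
#' `0-9A-Za-z` (case-sensitive), missing is `?`. The writer/reader pair
#' round-trips losslessly.
#'
#' @param chars A `multistate_character` or a named list of them sharing one
#'   taxon universe (taxa absent from a character are written as missing).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(chars, path) {
  if (inherits(chars, "multistate_character")) {
    chars <- stats::setNames(list(chars), attr(chars, "meaning"))
  }
  if (is.null(names(chars)) || anyDuplicated(names(chars)))
    stop("characters must be uniquely named by meaning")
  taxa <- sort(unique(unlist(lapply(chars, names))))
  symset <- state_symbols()
  cols <- vapply(chars, function(ch) {
    s <- ch[taxa]
    if (any(!is.na(s) & s >= length(symset)))
      stop("more than ", length(symset), " states in one character")
    ifelse(is.na(s), "?", symset[s + 1L])
  }, character(length(taxa)))
  cols <- matrix(cols, nrow = length(taxa))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), length(chars)),
    paste0("  FORMAT DATATYPE=STANDARD SYMBOLS=\"",
           paste(state_symbols(), collapse = ""), "\" MISSING=?;"),
    sprintf("  CHARSTATELABELS %s;",
            paste(sprintf("%d %s", seq_along(chars), names(chars)),
                  collapse = ", ")),
    "  MATRIX",
    sprintf("    %s %s", format(taxa), apply(cols, 1, paste, collapse = "")),
    "  ;",
    "END;")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a NEXUS standard-data matrix of multistate characters
#'
#' @param path NEXUS file written by [write_character_matrix()] (or any
#'   standard-data matrix with one-symbol states and `?` for missing).
#' @return Named list of `multistate_character` objects.
#' @export
read_character_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^#NEXUS", lines[1], ignore.case = TRUE))
    stop(path, " is not a NEXUS file")
  lab_line <- grep("CHARSTATELABELS", lines, ignore.case = TRUE, value = TRUE)
  m_start <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  m_end <- grep("^\\s*;\\s*$", lines)
  m_end <- m_end[m_end > m_start[1]][1]
  if (!length(m_start) || is.na(m_end)) stop("no MATRIX block in ", path)
  rows <- trimws(lines[(m_start[1] + 1L):(m_end - 1L)])
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\\s+")
  taxa <- vapply(parts, `[[`, "", 1L)
  symb <- strsplit(vapply(parts, function(p) p[[length(p)]], ""), "")
  nch <- unique(lengths(symb))
  if (length(nch) != 1L) stop("ragged character matrix in ", path)
  meanings <- sprintf("char%d", seq_len(nch))
  if (length(lab_line)) {
    body <- sub(".*CHARSTATELABELS", "", lab_line[1], ignore.case = TRUE)
    body <- sub(";\\s*$", "", body)
    items <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    for (it in items) meanings[as.integer(it[1])] <- it[2]
  }
  symset <- state_symbols()
  out <- lapply(seq_len(nch), function(j) {
    sym <- vapply(symb, `[[`, "", j)
    st <- match(sym, symset) - 1L
    if (any(is.na(st) & sym != "?"))
      stop("unknown state symbol in ", path, ": ",
           paste(unique(sym[is.na(st) & sym != "?"]), collapse = " "))
    multistate_character(stats::setNames(st, taxa), meanings[j])
  })
  stats::setNames(out, meanings)
}
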