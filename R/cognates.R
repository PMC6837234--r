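#' Normalize a word form into a segmental string
#'
#' Applies Unicode NFC normalization, case folding and whitespace stripping,
#' then user-supplied substitution rules (e.g. digraph -> segment) in
#' longest-match-first order. The result feeds [edit_distance()]; when a
#' curated phonetic transcription exists it should be used instead.
#'
#' @param form Non-empty orthographic string (vectorized).
#' @param rules Optional named character vector of substitutions applied after
#'   normalization, e.g. `c(sz = "S", cz = "C")`; longer patterns are applied
#'   first so digraphs win over their parts.
#' @return Normalized segmental string(s).
#' @export
#' @examples
#' normalize_form("Farfar")
#' normalize_form("brat", rules = c(br = "B"))
normalize_form <- function(form, rules = NULL) {
  if (any(is.na(form)) || any(!nzchar(trimws(form))))
    stop("cannot normalize an empty form")
  x <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(form))
  x <- gsub("\\s+", "", x)
  if (length(rules)) {
    if (is.null(names(rules)) || !all(nzchar(names(rules))))
      stop("substitution rules must be named by the pattern they replace")
    for (pat in names(rules)[order(-nchar(names(rules)), names(rules))])
      x <- gsub(pat, rules[[pat]], x, fixed = TRUE)
  }
  x
}

#' Normalized Levenshtein distance between two segmental strings
#'
#' Unit-cost Levenshtein edit distance divided by the length of the longer
#' string, so values lie in `[0, 1]`.
#'
#' @param a,b Non-empty strings.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' edit_distance("farfar", "morfar")  # 2/6
edit_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b) || is.na(a) || is.na(b))
    stop("edit_distance requires non-empty strings")
  as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

#' Pairwise normalized edit distances
#'
#' @param forms Character vector of non-empty segmental strings; names (if
#'   any) label the matrix.
#' @return Symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
distance_matrix <- function(forms) {
  if (!length(forms)) stop("need at least one form")
  if (any(!nzchar(forms)) || anyNA(forms)) stop("forms must be non-empty")
  d <- utils::adist(forms)
  len <- nchar(forms)
  d <- d / outer(len, len, pmax)
  diag(d) <- 0
  dimnames(d) <- list(names(forms) %||% forms, names(forms) %||% forms)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## average distance between two clusters under the original-distance UPGMA
## criterion: mean over all cross pairs of the input matrix
avg_link <- function(d, i, j) mean(d[i, j, drop = FALSE])

#' Flat agglomerative clustering at a distance threshold
#'
#' Agglomerates items by the chosen linkage until the smallest inter-cluster
#' distance exceeds `theta` (default 0.4), the flat clustering used to turn
#' pairwise edit distances into cognate classes. Ties between candidate
#' merges are broken deterministically by the lexicographically smallest item
#' label involved.
#'
#' @param d Symmetric distance matrix in `[0, 1]` (zero diagonal), with
#'   dimnames labelling the items.
#' @param theta Stopping threshold in `(0, 1)`; default 0.4.
#' @param linkage `"average"` (UPGMA, the default), `"single"` or
#'   `"complete"`, for sensitivity analysis.
#' @return Integer vector of class labels (`1..k`, dense, numbered by each
#'   cluster's smallest item index), named by item label.
#' @export
flat_cluster <- function(d, theta = 0.4, linkage = c("average", "single",
                                                     "complete")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (any(abs(d - t(d)) > 1e-12)) stop("d must be symmetric")
  if (any(d < 0 | d > 1)) stop("distances must lie in [0, 1]")
  if (!(theta > 0 && theta < 1)) stop("theta must lie in (0, 1)")
  n <- nrow(d)
  labs <- rownames(d) %||% as.character(seq_len(n))
  link_fun <- switch(linkage,
    average  = function(i, j) mean(d[i, j, drop = FALSE]),
    single   = function(i, j) min(d[i, j, drop = FALSE]),
    complete = function(i, j) max(d[i, j, drop = FALSE]))
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1L) break
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- link_fun(clusters[[i]], clusters[[j]])
      key <- sort(labs[c(clusters[[i]], clusters[[j]])])[1]
      if (dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 && !is.null(best_key) && key < best_key)) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    if (best_d > theta) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  cl <- integer(n)
  ord <- order(vapply(clusters, min, 1L))
  for (c_idx in seq_along(ord)) cl[clusters[[ord[c_idx]]]] <- c_idx
  stats::setNames(cl, labs)
}

#' Cognate-class partition for one meaning
#'
#' Clusters the forms of one meaning into cognate classes: forms are
#' normalized (the `transcription` column wins over orthography when
#' present), pairwise normalized edit distances are computed, and flat
#' average-linkage clustering is cut at `theta`.
#'
#' @param words `data.frame` with columns `language`, `form` and optionally
#'   `transcription`, all rows belonging to one meaning.
#' @param meaning Meaning label.
#' @param theta Clustering threshold, default 0.4.
#' @param linkage Linkage flavour, see [flat_cluster()].
#' @param rules Optional substitution rules for [normalize_form()].
#' @param synonym_policy What to do when one language lists several forms for
#'   the meaning: `"first"` (keep the first listed, the default) or
#'   `"error"`.
#' @return A `cognate_partition`: data.frame with columns `meaning`,
#'   `language`, `form`, `class` (dense integers) and `provenance`
#'   (`"automatic"` here; `"override"` after [apply_overrides()]).
#' @export
code_cognates <- function(words, meaning, theta = 0.4,
                          linkage = "average", rules = NULL,
                          synonym_policy = c("first", "error")) {
  synonym_policy <- match.arg(synonym_policy)
  if (!nrow(words)) stop("no word forms for meaning ", meaning)
  dup <- duplicated(words$language)
  if (any(dup)) {
    if (synonym_policy == "error")
      stop("synonyms for one language in meaning ", meaning, ": ",
           paste(unique(words$language[dup]), collapse = ", "))
    words <- words[!dup, , drop = FALSE]
  }
  seg <- words$transcription
  if (is.null(seg)) seg <- rep(NA_character_, nrow(words))
  use_orth <- is.na(seg) | !nzchar(seg)
  seg[use_orth] <- words$form[use_orth]
  seg <- normalize_form(seg, rules)
  d <- distance_matrix(stats::setNames(seg, words$language))
  cl <- flat_cluster(d, theta = theta, linkage = linkage)
  out <- data.frame(meaning = meaning, language = words$language,
                    form = words$form, class = unname(cl),
                    provenance = "automatic", stringsAsFactors = FALSE)
  class(out) <- c("cognate_partition", "data.frame")
  out
}

#' Cognate partitions for every meaning of a word list
#'
#' @param wordlist A word-form table from [read_wordlist()].
#' @param theta,linkage,rules,synonym_policy Passed to [code_cognates()].
#' @param overrides Optional override table from [read_overrides()], applied
#'   per meaning via [apply_overrides()].
#' @return Named list of `cognate_partition` objects, one per meaning.
#' @export
code_all_cognates <- function(wordlist, theta = 0.4, linkage = "average",
                              rules = NULL, synonym_policy = "first",
                              overrides = NULL) {
  meanings <- unique(wordlist$meaning)
  out <- lapply(meanings, function(m) {
    p <- code_cognates(wordlist[wordlist$meaning == m, , drop = FALSE], m,
                       theta = theta, linkage = linkage, rules = rules,
                       synonym_policy = synonym_policy)
    if (!is.null(overrides)) p <- apply_overrides(p, overrides)
    p
  })
  stats::setNames(out, meanings)
}

#' Apply expert overrides to a cognate partition
#'
#' Rows of `overrides` whose (meaning, language, form) matches an occurrence
#' in the partition move that occurrence into the class named by the
#' override's `class` column: occurrences sharing an override label share a
#' class, and a label that equals an existing automatic class id joins that
#' class. Unmatched overrides produce a warning and are skipped. Class labels
#' are re-densified afterwards.
#'
#' @param partition A `cognate_partition`.
#' @param overrides Override table (columns meaning, language, form, class).
#' @return The updated `cognate_partition`.
#' @export
apply_overrides <- function(partition, overrides) {
  ov <- overrides[overrides$meaning == partition$meaning[1], , drop = FALSE]
  if (!nrow(ov)) return(partition)
  key <- paste(ov$language, ov$form, sep = "\r")
  if (anyDuplicated(key[!duplicated(paste(key, ov$class))]))
    stop("conflicting overrides for one occurrence in meaning ",
         partition$meaning[1])
  pkey <- paste(partition$language, partition$form, sep = "\r")
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    warning("override(s) for unknown occurrence skipped: ",
            paste(paste(ov$language[is.na(hit)], ov$form[is.na(hit)]),
                  collapse = "; "))
    ov <- ov[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  if (!nrow(ov)) return(partition)
  grp <- as.character(partition$class)
  grp[hit] <- paste0("ov\r", ov$class)
  # an override label equal to an automatic class id joins that class
  auto_ids <- as.character(partition$class[-hit])
  joins <- sub("^ov\r", "", grp[hit])
  grp[hit][joins %in% auto_ids] <- joins[joins %in% auto_ids]
  # renumber by smallest member index for determinism
  first_ix <- vapply(split(seq_along(grp), grp), min, 1L)
  relabel <- rank(first_ix)
  partition$class <- as.integer(relabel[grp])
  partition$provenance[hit] <- "override"
  partition
}

#' Build a multistate character from a cognate partition
#'
#' Assigns each taxon in `taxa` the dense state index of its cognate class,
#' relabelling classes `0..k-1` by first appearance in the given taxon order;
#' taxa without a coded form become missing (`NA`).
#'
#' @param partition A `cognate_partition`.
#' @param taxa Character vector fixing the taxon order.
#' @return A [multistate_character()].
#' @export
build_character <- function(partition, taxa) {
  ix <- match(taxa, partition$language)
  extra <- setdiff(partition$language, taxa)
  if (length(extra))
    stop("partition covers languages outside taxa: ",
         paste(extra, collapse = ", "))
  cls <- partition$class[ix]
  seen <- unique(cls[!is.na(cls)])
  states <- match(cls, seen) - 1L
  multistate_character(stats::setNames(states, taxa),
                       meaning = partition$meaning[1])
}
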