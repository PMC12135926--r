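# Tokenization, POS tagging and stream truncation.
#
# Word tokens are case-folded and punctuation-only tokens are removed
# before any counting: the worked-example arithmetic (N = 22, p("the") =
# 3/22 for a sentence whose "The"/"the" both count) is only consistent
# with case-insensitive counting and punctuation exclusion.  Hyphen- and
# dash-joined compounds ("china–u.s.") stay single tokens, and a
# trailing period is retained on abbreviations that contain an internal
# period ("u.s.").

#' Tokenize raw text into word tokens
#'
#' Splits on whitespace, case-folds, strips leading/trailing punctuation
#' from each token and drops tokens that contain no alphanumeric
#' character.  Internal hyphens, dashes, apostrophes and abbreviation
#' periods are preserved.  Idempotent on already-tokenized,
#' space-joined text.
#'
#' @param raw_text a character string (may be empty).
#' @return Character vector of word tokens (possibly length 0).
#' @examples
#' tokenize("Languages and cultures are inseparable.")  # 5 tokens
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(trimws(raw_text))) return(character(0))
  raw <- strsplit(tolower(raw_text), "[[:space:]]+")[[1]]
  raw <- raw[nzchar(raw)]
  toks <- vapply(raw, clean_token, character(1), USE.NAMES = FALSE)
  toks[nzchar(toks)]
}

# Strip edge punctuation from a single whitespace-delimited chunk.  A
# trailing "." survives when the token keeps an earlier internal period
# (abbreviations such as "u.s.").
clean_token <- function(tok) {
  tok <- sub("^[^[:alnum:]]+", "", tok)
  repeat {
    if (!nzchar(tok) || !grepl("[^[:alnum:]]$", tok)) break
    last <- substr(tok, nchar(tok), nchar(tok))
    if (last == "." && grepl("\\.", substr(tok, 1L, nchar(tok) - 1L))) break
    tok <- substr(tok, 1L, nchar(tok) - 1L)
  }
  if (!grepl("[[:alnum:]]", tok)) "" else tok
}

#' The coarse POS categories used throughout the package
#'
#' @return Character vector of the twelve coarse tags.
#' @export
coarse_tagset <- function() {
  c("Det", "Num", "Noun", "Aux", "Verb", "Adj",
    "Prep", "Conj", "Pron", "Adv", "Part", "Other")
}

#' Default mapping from Penn-Treebank tags to the coarse tagset
#'
#' A total function on the Penn tagset (plus identity entries for the
#' coarse tags themselves, so already-coarse streams pass through
#' unchanged).
#'
#' @return Named character vector: names are fine tags, values coarse
#'   categories.
#' @export
default_tagset_mapping <- function() {
  penn <- c(
    DT = "Det", PDT = "Det", WDT = "Det",
    CD = "Num",
    NN = "Noun", NNS = "Noun", NNP = "Noun", NNPS = "Noun",
    MD = "Aux",
    VB = "Verb", VBD = "Verb", VBG = "Verb", VBN = "Verb",
    VBP = "Verb", VBZ = "Verb",
    JJ = "Adj", JJR = "Adj", JJS = "Adj",
    IN = "Prep", TO = "Prep",
    CC = "Conj",
    PRP = "Pron", `PRP$` = "Pron", WP = "Pron", `WP$` = "Pron",
    EX = "Pron",
    RB = "Adv", RBR = "Adv", RBS = "Adv", WRB = "Adv",
    RP = "Part", POS = "Part",
    FW = "Other", UH = "Other", SYM = "Other", LS = "Other"
  )
  coarse <- stats::setNames(coarse_tagset(), coarse_tagset())
  c(penn, coarse)
}

#' Map a tag stream to the coarse tagset
#'
#' @param tags character vector of fine-grained tags.
#' @param mapping named character vector (fine tag -> coarse tag);
#'   default [default_tagset_mapping()].
#' @return Character vector of coarse tags, same length as `tags`.
#' @export
map_to_coarse <- function(tags, mapping = default_tagset_mapping()) {
  stopifnot(is.character(tags), is.character(mapping),
            !is.null(names(mapping)))
  hit <- match(tags, names(mapping))
  if (anyNA(hit)) {
    bad <- unique(tags[is.na(hit)])
    stop("tag(s) not in the tagset mapping: ",
         paste(sQuote(bad), collapse = ", "))
  }
  unname(mapping[hit])
}

# Closed-class lexicons for the built-in tagger.
.tagger_lexicon <- local({
  lex <- list(
    Det  = c("the", "a", "an", "this", "that", "these", "those", "all",
             "both", "each", "every", "either", "neither", "some",
             "any", "no", "another", "such"),
    Aux  = c("will", "would", "can", "could", "may", "might", "shall",
             "should", "must", "am", "is", "are", "was", "were", "be",
             "been", "being", "do", "does", "did", "have", "has",
             "had"),
    Prep = c("of", "in", "on", "at", "by", "for", "with", "from", "to",
             "into", "onto", "about", "over", "under", "between",
             "among", "through", "during", "against", "within",
             "without", "across", "toward", "towards", "upon", "per",
             "amid", "despite"),
    Conj = c("and", "or", "but", "nor", "so", "yet", "because",
             "although", "though", "while", "whereas", "if", "unless",
             "since", "when", "as"),
    Pron = c("i", "you", "he", "she", "it", "we", "they", "me", "him",
             "her", "us", "them", "my", "your", "his", "its", "our",
             "their", "mine", "yours", "hers", "ours", "theirs", "who",
             "whom", "whose", "which", "what", "itself", "themselves"),
    Num  = c("one", "two", "three", "four", "five", "six", "seven",
             "eight", "nine", "ten", "eleven", "twelve", "dozen",
             "hundred", "thousand", "million", "billion"),
    Adv  = c("very", "quite", "too", "also", "then", "now", "here",
             "there", "however", "thus", "often", "never", "always",
             "already", "again", "soon", "still"),
    Part = c("not", "n't", "'s")
  )
  m <- rep(names(lex), lengths(lex))
  stats::setNames(m, unlist(lex, use.names = FALSE))
})

#' Built-in deterministic POS tagger (coarse tags)
#'
#' A lightweight lexicon-and-suffix tagger: closed-class words are
#' looked up in a small English lexicon, digits become `Num`, then
#' suffix heuristics assign `Adv`, `Verb` or `Adj`, with `Noun` as the
#' fallback.  It is a deterministic stand-in for a full statistical
#' tagger, adequate for controlled experiments; any function mapping a
#' token vector to a same-length tag vector can replace it via the
#' `tagger` argument of [pos_tag()].
#'
#' @param tokens character vector of case-folded word tokens.
#' @return Character vector of coarse tags, one per token.
#' @export
default_tagger <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  tags <- unname(.tagger_lexicon[tokens])
  open <- is.na(tags)
  if (any(open)) {
    t <- tokens[open]
    g <- rep("Noun", length(t))
    g[grepl("[0-9]", t)] <- "Num"
    g[grepl("(ing|ed|ise|ize|ises|izes|ated)$", t) & nchar(t) > 4] <- "Verb"
    g[grepl("(al|ous|ive|able|ible|ic|ful|less|ent|ant|ary|ian)$", t) &
        nchar(t) > 4] <- "Adj"
    g[grepl("ly$", t) & nchar(t) > 3] <- "Adv"
    tags[open] <- g
  }
  tags
}

#' Tag a token stream with a pluggable tagger
#'
#' @param tokens character vector of word tokens (non-empty).
#' @param tagger function from token vector to tag vector; default
#'   [default_tagger()].  The same tagger on the same tokens must
#'   return the same tags (determinism contract); a tagger returning
#'   the wrong number of tags is rejected.
#' @return Character vector of tags, one per token.
#' @export
pos_tag <- function(tokens, tagger = default_tagger) {
  stopifnot(is.character(tokens), is.function(tagger))
  if (length(tokens) == 0L) stop("cannot tag an empty token stream")
  tags <- tagger(tokens)
  if (!is.character(tags) || length(tags) != length(tokens)) {
    stop("tagger returned ", length(tags), " tags for ",
         length(tokens), " tokens")
  }
  tags
}

#' Truncate paired token/tag streams to a fixed window
#'
#' Keeps the first `min(length, limit)` positions of both streams.
#' Documents shorter than the limit are retained and flagged rather
#' than dropped (dropping is a corpus-level policy, see
#' [build_feature_table()]).
#'
#' @param tokens,tags equal-length character vectors.
#' @param limit maximum number of word tokens to keep (default 500).
#' @return List with `tokens`, `tags` and `short_text_flag` (TRUE when
#'   the original stream was shorter than `limit`).
#' @export
truncate_streams <- function(tokens, tags, limit = 500L) {
  if (length(tokens) != length(tags)) {
    stop("token and tag streams have unequal lengths (",
         length(tokens), " vs ", length(tags), ")")
  }
  stopifnot(length(limit) == 1L, is.finite(limit))
  if (limit < 1) stop("truncation limit must be at least 1")
  keep <- seq_len(min(length(tokens), limit))
  list(tokens = tokens[keep], tags = tags[keep],
       short_text_flag = length(tokens) < limit)
}
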