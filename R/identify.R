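#' Candidate filtering and consensus coding-potential classification
#'
#' Novel transcripts are screened in two steps. First, transcripts shorter
#' than a minimum length (default 200 nt, the conventional lncRNA floor)
#' and transcripts matching a known-mRNA id list are discarded. Second,
#' five independent coding-potential verdicts per transcript -- three
#' numeric scores (CPC-, CNCI- and LGC-style, sign convention: > 0 coding,
#' < 0 noncoding) and two protein-database hit flags (Pfam, SwissProt) --
#' are combined by majority vote: a transcript is called a novel mRNA when
#' at least three of the five verdicts are coding AND at least one protein
#' database hit is present; it is called a novel lncRNA when at least three
#' verdicts are noncoding; anything else is ambiguous and excluded from
#' both downstream sets.
#'
#' @name lncrna_identify
NULL

#' Length/known filtering of candidate transcripts
#'
#' @param transcripts a `transcript_set`.
#' @param known_ids character vector of known mRNA transcript ids.
#' @param min_length minimum transcript length in nt (default 200;
#'   transcripts of exactly `min_length` are retained).
#' @return list with `retained` (a `transcript_set`) and `discarded`
#'   (data frame `transcript_id`, `reason` in `known_mRNA`/`too_short`).
#' @export
filter_candidates <- function(transcripts, known_ids = character(),
                              min_length = 200L) {
  stopifnot(min_length >= 1L)
  if (nrow(transcripts) == 0L) {
    warning("empty transcript collection; nothing to filter")
    return(list(retained = transcripts,
                discarded = data.frame(transcript_id = character(),
                                       reason = character())))
  }
  known <- transcripts$transcript_id %in% known_ids
  short <- transcripts$length < min_length
  reason <- ifelse(known, "known_mRNA",
                   ifelse(short, "too_short", NA_character_))
  drop <- !is.na(reason)
  list(retained = new_transcript_set(transcripts[!drop, , drop = FALSE]),
       discarded = data.frame(transcript_id = transcripts$transcript_id[drop],
                              reason = reason[drop],
                              stringsAsFactors = FALSE))
}

#' Read a coding-evidence table
#'
#' Tab-separated with header `transcript_id cpc cnci lgc pfam swissprot`;
#' flags coded 0/1.
#'
#' @param path file path.
#' @return data frame with columns `transcript_id`, `cpc_score`,
#'   `cnci_score`, `lgc_score`, `pfam_hit`, `swissprot_hit`.
#' @export
read_coding_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cpc", "cnci", "lgc", "pfam", "swissprot")
  if (!all(need %in% names(df)))
    stop("evidence table must have columns: ", paste(need, collapse = " "))
  data.frame(transcript_id = as.character(df$transcript_id),
             cpc_score = as.numeric(df$cpc),
             cnci_score = as.numeric(df$cnci),
             lgc_score = as.numeric(df$lgc),
             pfam_hit = as.logical(df$pfam),
             swissprot_hit = as.logical(df$swissprot),
             stringsAsFactors = FALSE)
}

#' Five-way consensus coding-potential classification
#'
#' @param evidence data frame as from [read_coding_evidence()]. Records
#'   with any missing score are rejected with a warning.
#' @param vote_min votes needed on a side to call it (default 3 of 5).
#' @param zero_as_coding how to vote a score of exactly 0 (default
#'   `FALSE`: noncoding).
#' @return data frame `transcript_id`, `coding_votes` (0-5), `call` in
#'   `novel_mRNA`/`novel_lncRNA`/`ambiguous`.
#' @export
consensus_classify <- function(evidence, vote_min = 3L,
                               zero_as_coding = FALSE) {
  scores <- cbind(evidence$cpc_score, evidence$cnci_score, evidence$lgc_score)
  bad <- apply(scores, 1L, anyNA) |
    is.na(evidence$pfam_hit) | is.na(evidence$swissprot_hit)
  if (any(bad)) {
    warning(sum(bad), " evidence record(s) rejected for missing values: ",
            paste(utils::head(evidence$transcript_id[bad], 5), collapse = ", "))
    evidence <- evidence[!bad, , drop = FALSE]
    scores <- scores[!bad, , drop = FALSE]
  }
  vote_score <- if (zero_as_coding) scores >= 0 else scores > 0
  votes <- rowSums(vote_score) + evidence$pfam_hit + evidence$swissprot_hit
  db_hit <- evidence$pfam_hit | evidence$swissprot_hit
  call <- ifelse(votes >= vote_min & db_hit, "novel_mRNA",
                 ifelse(5L - votes >= vote_min, "novel_lncRNA", "ambiguous"))
  data.frame(transcript_id = evidence$transcript_id,
             coding_votes = as.integer(votes), call = call,
             stringsAsFactors = FALSE)
}
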