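#' The five-domain / 51-sub-domain behavioral taxonomy
#'
#' Returns the fixed behavioral classification used throughout the package:
#' five major domains (Action, Cognition, Emotion, Interoception,
#' Perception) partitioned into 51 behavioral sub-domains, as used by the
#' BrainMap coding scheme. Sub-domain ids are stable integers 1--51 in
#' domain order; the \code{reference_n} column carries the published 2012
#' per-sub-domain focus tallies purely as descriptive metadata (it is never
#' used in any computation).
#'
#' @return An object of class \code{behavior_taxonomy}: a data.frame with
#'   columns \code{id} (integer 1--51), \code{domain} (factor with the five
#'   domain levels), \code{name} (character, e.g. \code{"Language:Semantics"})
#'   and \code{reference_n} (integer, descriptive only).
#' @examples
#' tax <- behavior_taxonomy()
#' nrow(tax)           # 51
#' table(tax$domain)
#' @export
behavior_taxonomy <- function() {
  domains <- c("Action", "Cognition", "Emotion", "Interoception", "Perception")
  entries <- list(
    Action = c(
      "Execution:Other" = 8518L, "Execution:Speech" = 3399L,
      "Imagination" = 1244L, "Inhibition" = 2519L, "Motor:Learning" = 832L,
      "Observation" = 972L, "Other" = 11L, "Preparation" = 346L,
      "Rest" = 1611L),
    Cognition = c(
      "Attention" = 10995L, "Language:Orthography" = 2011L,
      "Language:Other" = 1204L, "Language:Phonology" = 1621L,
      "Language:Semantics" = 7593L, "Language:Speech" = 7244L,
      "Language:Syntax" = 655L, "Memory:Explicit" = 7002L,
      "Memory:Other" = 50L, "Memory:Working" = 7819L, "Music" = 822L,
      "Other" = 8847L, "Reasoning" = 1387L, "Social" = 1562L,
      "Soma" = 581L, "Space" = 1935L, "Time" = 495L),
    Emotion = c(
      "Anger" = 507L, "Anxiety" = 577L, "Disgust" = 879L, "Fear" = 1311L,
      "Happiness:Humor" = 120L, "Happiness:Other" = 1060L,
      "Other" = 12821L, "Sadness" = 1167L),
    Interoception = c(
      "Air-hunger" = 236L, "Bladder" = 315L, "Hunger" = 386L,
      "Other" = 200L, "Sexuality" = 877L, "Sleep" = 260L,
      "Thermoregulation" = 29L, "Thirst" = 209L),
    Perception = c(
      "Audition" = 2850L, "Gustation" = 1173L, "Olfaction" = 400L,
      "Somesthesis:Other" = 2542L, "Somesthesis:Pain" = 3472L,
      "Vision:Color" = 201L, "Vision:Motion" = 2514L,
      "Vision:Other" = 2106L, "Vision:Shape" = 2995L)
  )
  tax <- data.frame(
    id = seq_len(sum(lengths(entries))),
    domain = factor(rep(domains, lengths(entries)), levels = domains),
    name = unlist(lapply(entries, names), use.names = FALSE),
    reference_n = unlist(entries, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  class(tax) <- c("behavior_taxonomy", "data.frame")
  tax
}

#' Number of behavioral sub-domains
#' @keywords internal
n_subdomains <- function() 51L

#' Normalize sub-domain identifiers to integer ids
#'
#' Accepts integer ids (1--51) or \code{"Domain:Name"} strings (e.g.
#' \code{"Cognition:Language:Semantics"}) and returns integer ids.
#' Plain names unique across domains (e.g. \code{"Imagination"}) are also
#' accepted.
#'
#' @param x integer or character vector of sub-domain identifiers.
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return integer vector of ids; unresolvable entries raise an error.
#' @export
normalize_subdomain_id <- function(x, taxonomy = behavior_taxonomy()) {
  if (is.numeric(x)) {
    id <- as.integer(x)
    bad <- which(is.na(id) | id < 1L | id > nrow(taxonomy) | id != x)
    if (length(bad))
      stopf("unknown sub-domain id(s): %s", paste(unique(x[bad]), collapse = ", "))
    return(id)
  }
  x <- as.character(x)
  full <- paste(taxonomy$domain, taxonomy$name, sep = ":")
  id <- match(x, full)
  # bare names, where unambiguous
  need <- is.na(id)
  if (any(need)) {
    counts <- table(taxonomy$name)
    uniq <- names(counts)[counts == 1L]
    m <- match(x[need], taxonomy$name)
    m[!(x[need] %in% uniq)] <- NA_integer_
    id[need] <- taxonomy$id[m]
  }
  # numeric strings
  need <- is.na(id) & grepl("^[0-9]+$", x)
  if (any(need)) id[need] <- normalize_subdomain_id(as.integer(x[need]), taxonomy)
  if (anyNA(id))
    stopf("unknown or ambiguous sub-domain identifier(s): %s",
          paste(unique(x[is.na(id)]), collapse = ", "))
  as.integer(id)
}

#' Export the taxonomy as CSV
#'
#' @param path output file path.
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return invisibly, the path.
#' @export
write_taxonomy <- function(path, taxonomy = behavior_taxonomy()) {
  utils::write.csv(as.data.frame(taxonomy), path, row.names = FALSE)
  invisible(path)
}
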