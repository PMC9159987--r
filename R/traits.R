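# Allele-trait association mining: which alleles (or lineage groups) are
# carried by all — and only — samples exhibiting a character state.

#' Associate character states with alleles or groups
#'
#' For every (character, state) pair, the *lenient* set is the intersection
#' of carrier allele sets over all samples showing the state (alleles present
#' in every state-sample); the *strict* set removes any allele also carried
#' by a sample of a different state of the same character. States with an
#' empty strict set are reported `undetermined = TRUE` (the association, if
#' any, is only lenient). At `granularity = "group"` alleles are replaced by
#' their lineage groups first, reproducing group-level associations such as
#' venation forms.
#'
#' @param characters long-format character matrix: `data.frame` with columns
#'   `sample_id`, `character`, `state` (missing scores simply absent).
#' @param genotypes long genotype `data.frame`; carrier sets are taken from
#'   `locus`.
#' @param locus nuclear locus whose alleles are mined (default `"Knox3"`).
#' @param granularity `"allele"` or `"group"`.
#' @return a `data.frame` with columns `character`, `state`, `n_samples`,
#'   `strict`, `lenient` (comma-separated sets) and `undetermined`; ordering
#'   is independent of input sample order. Attribute `"audit"` records the
#'   self-check that every strict allele is present in all state-samples and
#'   absent elsewhere.
#' @export
associate_states <- function(characters, genotypes, locus = "Knox3",
                             granularity = c("allele", "group")) {
  granularity <- match.arg(granularity)
  stopifnot(all(c("sample_id", "character", "state") %in% names(characters)))
  gx <- genotypes[genotypes$locus_id == locus, ]
  carrier <- stats::setNames(lapply(seq_len(nrow(gx)), function(i) {
    al <- unique(gx$alleles[[i]])
    if (granularity == "group") unique(allele_group(al)) else al
  }), gx$sample_id)
  missing <- setdiff(unique(characters$sample_id), names(carrier))
  if (length(missing) > 0L) {
    stop("sample(s) in character matrix without a genotype at ", locus, ": ",
         paste(sort(missing), collapse = ", "))
  }
  out <- list()
  audit_ok <- TRUE
  for (ch in sort(unique(characters$character))) {
    sub <- characters[characters$character == ch, ]
    states <- sort(unique(sub$state))
    if (length(states) < 2L) {
      stop("character '", ch, "' has fewer than 2 observed states")
    }
    for (st in states) {
      in_ids <- sort(unique(sub$sample_id[sub$state == st]))
      out_ids <- sort(unique(sub$sample_id[sub$state != st]))
      lenient <- Reduce(intersect, carrier[in_ids])
      outside <- unique(unlist(carrier[out_ids]))
      strict <- setdiff(lenient, outside)
      # soundness self-audit against the raw matrix
      for (a in strict) {
        ok <- all(vapply(carrier[in_ids], function(s) a %in% s, logical(1L))) &&
          !any(vapply(carrier[out_ids], function(s) a %in% s, logical(1L)))
        if (!ok) audit_ok <- FALSE
      }
      out[[length(out) + 1L]] <- data.frame(
        character = ch, state = st, n_samples = length(in_ids),
        strict = fmt_set(sort(strict)), lenient = fmt_set(sort(lenient)),
        undetermined = length(strict) == 0L, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "audit") <- audit_ok
  res
}
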