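# Molecular-pathology KRAS annotation parsing and grouping policies.

#' Parse a KRAS annotation string
#'
#' Recognizes the three annotation forms found in molecular pathology
#' reports for this analysis:
#' * missense: `"G12D (c.35G > A) exon 2"` — amino-acid change, cDNA
#'   change, exon; whitespace and case tolerant;
#' * whole-gene amplification: `"Whole gene amplification 12p12.1,
#'   FC: 23.0 (Inv. Panel)"` — optional fold change and panel suffix;
#' * empty / `NA` / `"wild type"` / `"WT"` — wild type.
#'
#' Unrecognized non-empty strings raise an error naming the offending
#' value; nothing is silently coerced to wild type.
#'
#' @param raw Character vector of annotation strings.
#' @return Data frame with one row per input: columns `raw`, `kind`
#'   (`"missense"`, `"amplification"`, `"wild_type"`), `aa_change`,
#'   `codon`, `cdna`, `exon`, `locus`, `fold_change`, `panel`.
#' @export
#' @examples
#' parse_kras("G12D (c.35G > A) exon 2")$codon # 12
parse_kras <- function(raw) {
  res <- lapply(raw, parse_kras_one)
  do.call(rbind, res)
}

parse_kras_one <- function(raw) {
  out <- data.frame(raw = if (is.na(raw)) "" else raw,
                    kind = NA_character_, aa_change = NA_character_,
                    codon = NA_integer_, cdna = NA_character_,
                    exon = NA_integer_, locus = NA_character_,
                    fold_change = NA_real_, panel = NA_character_,
                    stringsAsFactors = FALSE)
  s <- if (is.na(raw)) "" else trimws(raw)
  if (!nzchar(s) || grepl("^(wild[ -]?type|wt)$", s, ignore.case = TRUE)) {
    out$kind <- "wild_type"
    return(out)
  }
  mis <- regmatches(s, regexec(
    "^([A-Z])\\s*([0-9]+)\\s*([A-Z])\\s*\\(\\s*c\\.\\s*([0-9]+\\s*[A-Za-z]+\\s*>\\s*[A-Za-z]+)\\s*\\)\\s*[Ee]xon\\s*([0-9]+)$",
    s))[[1]]
  if (length(mis)) {
    out$kind <- "missense"
    out$aa_change <- paste0(mis[2], mis[3], mis[4])
    out$codon <- as.integer(mis[3])
    out$cdna <- gsub("\\s+", "", mis[5])
    out$exon <- as.integer(mis[6])
    return(out)
  }
  amp <- regmatches(s, regexec(
    "^[Ww]hole\\s+gene\\s+amplification\\s*([0-9]+[pq][0-9.]+)?\\s*(?:,\\s*FC\\s*:\\s*([0-9.]+))?\\s*(?:\\(([^)]*)\\))?$",
    s))[[1]]
  if (length(amp)) {
    out$kind <- "amplification"
    out$locus <- if (nzchar(amp[2])) amp[2] else NA_character_
    out$fold_change <- if (nzchar(amp[3])) as.numeric(amp[3]) else NA_real_
    out$panel <- if (nzchar(amp[4])) amp[4] else NA_character_
    return(out)
  }
  stop("unrecognized KRAS annotation: \"", raw, "\"", call. = FALSE)
}

#' Format parsed KRAS annotations back to canonical strings
#'
#' Inverse of [parse_kras()] up to whitespace normalization; parsing the
#' formatted string recovers the same fields.
#'
#' @param parsed Data frame from [parse_kras()].
#' @return Character vector of canonical annotation strings (empty string
#'   for wild type).
#' @export
format_kras <- function(parsed) {
  vapply(seq_len(nrow(parsed)), function(i) {
    p <- parsed[i, ]
    switch(p$kind,
      wild_type = "",
      missense = sprintf("%s (c.%s) exon %d",
                         p$aa_change,
                         sub(">", " > ", p$cdna, fixed = TRUE),
                         p$exon),
      amplification = {
        s <- "Whole gene amplification"
        if (!is.na(p$locus)) s <- paste(s, p$locus)
        if (!is.na(p$fold_change)) {
          s <- sprintf("%s, FC: %s", s, format(p$fold_change))
        }
        if (!is.na(p$panel)) s <- sprintf("%s (%s)", s, p$panel)
        s
      }
    )
  }, character(1))
}

#' Binary mutation labels under the two amplification grouping policies
#'
#' Missense annotations are always labelled 1 (mutant) and wild type always
#' 0. Whole-gene amplification cases are grouped with wild type (label 0)
#' under the primary policy `"amp_with_wt"` and with the mutants (label 1)
#' under `"amp_with_mut"`.
#'
#' @param parsed Data frame from [parse_kras()] (or a character vector of
#'   `kind` values).
#' @param policy `"amp_with_wt"` (default) or `"amp_with_mut"`.
#' @return Integer vector of 0/1 labels.
#' @export
kras_labels <- function(parsed, policy = c("amp_with_wt", "amp_with_mut")) {
  policy <- match.arg(policy)
  kind <- if (is.data.frame(parsed)) parsed$kind else parsed
  stopifnot(all(kind %in% c("missense", "amplification", "wild_type")))
  amp_label <- if (policy == "amp_with_mut") 1L else 0L
  ifelse(kind == "missense", 1L,
         ifelse(kind == "amplification", amp_label, 0L))
}

#' Census of missense codons
#'
#' Histogram of the protein codon positions of the missense annotations;
#' amplifications and wild type are excluded.
#'
#' @param parsed Data frame from [parse_kras()].
#' @return Named integer vector (names are codon numbers), empty when no
#'   missense annotations are present.
#' @export
codon_census <- function(parsed) {
  codons <- parsed$codon[parsed$kind == "missense"]
  if (!length(codons)) return(integer(0))
  tab <- table(codons)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Expected number of mislabeled lesions
#'
#' When only a subset of lesions has mutation status confirmed from the
#' lesion's own biopsy, the remainder inherit a patient-level status with
#' some discordance probability; the expected count of mislabeled lesions is
#' `discordance_rate * (n_total - n_confirmed)`.
#'
#' @param n_total Total number of lesions (default 60).
#' @param n_confirmed Lesions with status from their own biopsy (default
#'   31).
#' @param discordance_rate Primary/metastasis discordance probability
#'   (default 0.1).
#' @return Expected mislabeled-lesion count.
#' @export
#' @examples
#' expected_mislabeled() # 2.9
expected_mislabeled <- function(n_total = 60, n_confirmed = 31,
                                discordance_rate = 0.1) {
  stopifnot(n_confirmed <= n_total, discordance_rate >= 0,
            discordance_rate <= 1)
  discordance_rate * (n_total - n_confirmed)
}
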