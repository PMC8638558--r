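# internal helpers shared across modules

RNA_BASES <- c("A", "C", "G", "U")

# split a sequence string into a character vector of single bases
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# DNA -> RNA on read; everything upper-case
as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

check_rna_alphabet <- function(sequence, id = "<sequence>") {
  bad <- setdiff(unique(seq_chars(sequence)), c(RNA_BASES, "N"))
  if (length(bad) > 0) {
    abort(sprintf("transcript '%s': invalid characters in sequence: %s",
                  id, paste(bad, collapse = ", ")))
  }
  invisible(sequence)
}

# integer codes used by the C++ engines: A=0 C=1 G=2 U=3 N=4
encode_rna <- function(sequence) {
  m <- match(seq_chars(sequence), c(RNA_BASES, "N")) - 1L
  if (anyNA(m)) abort("invalid character in RNA sequence")
  m
}

# region of a 0-based position given half-open CDS bounds
region_of <- function(pos, cds_start, cds_end) {
  dplyr::case_when(
    pos < cds_start ~ "utr5",
    pos < cds_end ~ "cds",
    TRUE ~ "utr3"
  )
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)

# write a tibble as TSV with a commented header line carrying provenance
write_tsv_commented <- function(df, path, params = NULL) {
  meta <- sprintf("# ribostruct %s | %s",
                  as.character(utils::packageVersion("ribostruct")),
                  if (is.null(params)) "" else
                    paste(names(params), unlist(params), sep = "=",
                          collapse = " "))
  writeLines(meta, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

# area under the ROC curve via the rank (Mann-Whitney) identity;
# `positive` is a logical vector, `score` the predictor
rank_auc <- function(score, positive) {
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]
  positive <- as.logical(positive[ok])
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
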