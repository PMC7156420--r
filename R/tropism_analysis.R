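# parse a trinucleotide class label: "CAN>CTN" (5'-anchored) or
# "NTG>NAG" (3'-anchored) into its ref/alt/flank constraint
parse_tri_class <- function(label) {
  m <- regmatches(label, regexec("^([ACGTN])([ACGT])([ACGTN])>([ACGTN])([ACGT])([ACGTN])$",
                                 label))[[1]]
  if (length(m) == 0L) stop2(sprintf("cannot parse class label '%s'", label))
  f5 <- m[2]; ref <- m[3]; f3 <- m[4]; alt <- m[6]
  if (m[5] != "N" && m[5] != f5)
    stop2(sprintf("inconsistent flanks in '%s'", label))
  list(ref = ref, alt = alt,
       context5 = if (f5 == "N") NA_character_ else f5,
       context3 = if (f3 == "N") NA_character_ else f3)
}

tri_class_rows <- function(tab, label) {
  cls <- parse_tri_class(label)
  sel <- tab$ref == cls$ref & tab$alt == cls$alt
  if (!is.na(cls$context5)) sel <- sel & !is.na(tab$context5) &
      tab$context5 == cls$context5
  if (!is.na(cls$context3)) sel <- sel & !is.na(tab$context3) &
      tab$context3 == cls$context3
  sel
}

#' Strand-asymmetry summary of a substitution class pair
#'
#' For each class of a complementary pair (e.g. `CAN>CTN` and its
#' reverse-complement `NTG>NAG`, which mark the same kind of genomic site
#' read on opposite strands), averages the corrected mutation frequency over
#' the amplicon positions qualifying for that class within each sample, then
#' reports mean and SEM across samples.
#'
#' @param tables named list of [compute_frequencies()] tables from one
#'   amplicon/tissue/treatment group.
#' @param class_pair two trinucleotide class labels (default
#'   `c("CAN>CTN", "NTG>NAG")`).
#' @param use_corrected average `mf_corrected` (default) or raw `mf`.
#' @return data.frame with one row per class: `class`, `mean`, `sem`,
#'   `n_samples`, `n_positions`. A class with no qualifying position gets
#'   `NA` mean and `n_positions = 0`.
#' @export
strand_bias_summary <- function(tables, class_pair = c("CAN>CTN", "NTG>NAG"),
                                use_corrected = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  col <- if (use_corrected) "mf_corrected" else "mf"
  out <- lapply(class_pair, function(label) {
    per_sample <- vapply(tables, function(tab) {
      sel <- tri_class_rows(tab, label)
      if (!any(sel)) return(NA_real_)
      mean(tab[[col]][sel], na.rm = TRUE)
    }, numeric(1))
    npos <- if (length(tables))
      sum(tri_class_rows(tables[[1]], label)) else 0L
    data.frame(class = label,
               mean = if (all(is.na(per_sample))) NA_real_
                      else mean(per_sample, na.rm = TRUE),
               sem = sem(per_sample),
               n_samples = sum(!is.na(per_sample)),
               n_positions = npos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign genes to expression quartiles
#'
#' Genes are sorted by mean FPKM across replicates (stable sort, ties broken
#' by gene identifier) and split into 4 bins of near-equal size; when the
#' gene count is not divisible by 4 the remainder goes to the lower
#' (lower-expression) quartiles. Quartile 1 is the lowest-expressed.
#'
#' @param expression data.frame with `gene` and `fpkm_rep*` columns.
#' @return data.frame with `gene`, `mean_fpkm`, `quartile`.
#' @export
assign_expression_quartiles <- function(expression) {
  fpkm_cols <- grep("^fpkm", names(expression), value = TRUE)
  if (length(fpkm_cols) == 0L) stop2("no fpkm_rep* columns found")
  n <- nrow(expression)
  if (n < 4L) stop2("need at least 4 genes to form quartiles")
  mean_fpkm <- rowMeans(expression[, fpkm_cols, drop = FALSE])
  ord <- order(mean_fpkm, expression$gene)
  sizes <- rep(n %/% 4L, 4L) + (seq_len(4L) <= n %% 4L)
  quartile <- integer(n)
  quartile[ord] <- rep.int(1:4, sizes)
  data.frame(gene = expression$gene, mean_fpkm = mean_fpkm,
             quartile = quartile, stringsAsFactors = FALSE)
}

#' Expression-quartile strand-bias analysis
#'
#' Bins genes into expression quartiles, sums the CAN>CTN transversions on
#' each strand per tumor within each quartile, and summarises the cohort as
#' mean +/- SEM across tumors per quartile and strand. Mutation records
#' whose gene lacks expression data are dropped (and counted in the
#' `dropped` element).
#'
#' @param expression data.frame with `gene` and `fpkm_rep*` columns.
#' @param mutations data.frame with `tumor`, `gene`, `strand`
#'   (`"non_transcribed"`/`"transcribed"`), `class`, `count`.
#' @param class restrict to this substitution class (default `"CAN>CTN"`).
#' @return list with `assignments` (gene -> quartile), `bin_table` (tumor x
#'   quartile x strand sums, complete grid), `summary` (quartile, strand,
#'   mean, sem, n_tumors) and `dropped` (number of dropped records).
#' @export
expression_quartile_bias <- function(expression, mutations,
                                     class = "CAN>CTN") {
  assignments <- assign_expression_quartiles(expression)
  mut <- mutations[mutations$class == class, , drop = FALSE]
  known <- mut$gene %in% assignments$gene
  dropped <- sum(!known)
  if (dropped > 0L)
    message(sprintf("dropping %d mutation records with no expression data",
                    dropped))
  mut <- mut[known, , drop = FALSE]
  mut$quartile <- assignments$quartile[match(mut$gene, assignments$gene)]
  tumors <- sort(unique(mutations$tumor))
  grid <- expand.grid(tumor = tumors, quartile = 1:4,
                      strand = c("non_transcribed", "transcribed"),
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ tumor + quartile + strand, data = mut,
                          FUN = sum)
  bin <- merge(grid, agg, all.x = TRUE)
  bin$count[is.na(bin$count)] <- 0
  bin <- bin[order(bin$tumor, bin$quartile, bin$strand), ]
  rownames(bin) <- NULL
  summ <- do.call(rbind, lapply(split(bin, list(bin$quartile, bin$strand)),
    function(d) data.frame(quartile = d$quartile[1], strand = d$strand[1],
                           mean = mean(d$count), sem = sem(d$count),
                           n_tumors = nrow(d), stringsAsFactors = FALSE)))
  summ <- summ[order(summ$strand, summ$quartile), ]
  rownames(summ) <- NULL
  list(assignments = assignments, bin_table = bin, summary = summ,
       dropped = dropped)
}
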