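#!/usr/bin/env Rscript
# Cross-lesion overlap. Two questions:
#  (1) in the matched three-class layout, how do the ADH and DCIS gene
#      lists relate (common / exclusive / subset)?
#  (2) the worked example on the published comparison table: the HELU list
#      and the ADH/DCIS list share exactly 5 genes, all changing in the
#      same direction.

suppressPackageStartupMessages(library(lesionDE))

read_sig <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(gene = "character"))
  df$gene[df$significant]
}

dir <- "results/simulated/triplet"
adh <- read_sig(file.path(dir, "de_ADH_vs_HN.tsv"))
dcis <- read_sig(file.path(dir, "de_DCIS_vs_HN.tsv"))
ov <- classify_overlap(adh, dcis, labels = c("ADH", "DCIS"))
write_overlap_report(ov, file.path(dir, "overlap_ADH_DCIS.tsv"))
print(ov)
sub <- check_subset(adh, dcis)
cat(sprintf("ADH list contained in DCIS list: %s (missing: %s)\n",
            sub$is_subset,
            if (length(sub$missing)) paste(sub$missing, collapse = ", ")
            else "none"))

cat("\n")
l <- published_de_lists()
pub <- classify_overlap(l$helu, l$adh_dcis, labels = c("HELU", "ADH/DCIS"),
                        fc_a = l$fc_helu, fc_b = l$fc_adh_dcis)
write_overlap_report(pub, "results/overlap_published.tsv")
print(pub)
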