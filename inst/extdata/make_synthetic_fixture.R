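# Regenerates c4_trait_matrix_synthetic.tsv.
#
# The original study's supplementary binary trait scoring is not
# redistributed with this package; this script builds a SYNTHETIC stand-in
# with the same shape (intermediate species x 16 traits, values 0/1/2) and a
# comparable ~50% missing-data burden. Intermediates are drawn as partial
# accumulations along two distinct trait orderings (emulating multiple
# evolutionary pathways, with monocots and eudicots biased to different
# orderings), then half of the entries are occluded. Deterministic: seed 20.
#
# Run from the repository root:  Rscript inst/extdata/make_synthetic_fixture.R

library(traitpaths)

traits <- c(
  "bs_enlargement", "vein_spacing_decrease", "gdc_bs_specificity",
  "bs_chloroplast_number", "bs_chloroplast_size", "co2_compensation_point",
  "pepc_activity", "pepc_m_specificity", "ppdk_activity",
  "ppdk_m_specificity", "decarboxylase_activity",
  "decarboxylase_bs_specificity", "mdh_activity", "mdh_m_specificity",
  "rubisco_activity_decrease", "rubisco_bs_specificity"
)
L <- length(traits)

meta <- read.delim("inst/extdata/c4_species_metadata.tsv",
                   colClasses = "character")
inter <- meta[meta$type == "C3-C4", ]

set.seed(20)
# two pathways: anatomy-first vs a variant swapping some early/mid traits
ord1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 11, 13, 10, 12, 14, 15, 16)
ord2 <- c(3, 1, 6, 2, 4, 5, 7, 9, 8, 10, 11, 13, 12, 14, 15, 16)
rows <- t(vapply(seq_len(nrow(inter)), function(i) {
  ord <- if (inter$lineage[i] == "monocot" || runif(1) < 0.3) ord2 else ord1
  step <- sample(seq_len(L - 1), 1)
  p <- integer(L)
  p[ord[seq_len(step)]] <- 1L
  p
}, integer(L)))
rownames(rows) <- inter$species

# occlude half of all entries, as in the real compilation's missing burden
occluded <- as_phenotype_matrix(occlude(rows, 0.5, seed = 21))

out <- data.frame(species = inter$species, type = inter$type,
                  occluded, check.names = FALSE)
colnames(out) <- c("species", "type", traits)
write.table(out, "inst/extdata/c4_trait_matrix_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
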