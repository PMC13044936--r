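# Mock VAR-Seq cohort workflow

A 35-step mock variant-calling workflow demonstrating scatter/gather
execution with hybrid command-line and R steps. Per-sample read QC,
trimming, alignment and gVCF-style variant calling (scatter) feed a
cohort-level joint genotyping step (gather), followed by filtering,
functional annotation, and downstream multi-modal analyses: gene-level
variant burden, toy pathway enrichment, and mapping of prioritized genes
to known drug targets. All heavy bioinformatics tools are replaced by
deterministic mock scripts operating on toy text data, so the complete
workflow runs offline in seconds; the analytical structure — not the
biology — is the point.

## Configuration

```{r step="load_config" kind="code"}
dir.create("results", showWarnings = FALSE)
targets <- read.delim("targets.tsv", comment.char = "#",
                      stringsAsFactors = FALSE)
cohort_samples <- targets$SampleName
cat("cohort of", length(cohort_samples), "samples\n")
```

```{r step="check_input" kind="code" deps="load_config"}
stopifnot(file.exists(targets$FileName),
          file.exists("data/reference.txt"),
          file.exists("data/pathways.tsv"),
          file.exists("data/drug_targets.tsv"))
cat("all input files present\n")
```

## Read quality assessment

Raw read statistics are computed per sample (scatter), then gathered
into a cohort QC table.

```{yaml step="fastq_stats" kind="cmd" deps="check_input"}
tool: param/mock_stats_raw.cwl
targets: targets.tsv
inputs:
  infile: _FileName_
```

```{r step="qc_report_raw" kind="code" deps="fastq_stats"}
files <- sort(Sys.glob("results/*.rawstats.txt"))
qc <- do.call(rbind, lapply(files, function(f) {
  x <- read.delim(f, stringsAsFactors = FALSE)
  data.frame(sample = sub("\\.rawstats\\.txt$", "", basename(f)),
             reads = x$value[x$metric == "lines"],
             bases = x$value[x$metric == "chars"])
}))
write.table(qc, "results/qc_raw.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

## Read preprocessing

Short reads are removed; QC is repeated on the trimmed files, whose
paths are inherited from the trimming step's declared outputs.

```{yaml step="trim_reads" kind="cmd" deps="check_input"}
tool: param/mock_trim.cwl
targets: targets.tsv
inputs:
  reads: _FileName_
```

```{yaml step="fastq_stats_trim" kind="cmd" deps="trim_reads"}
tool: param/mock_stats_trim.cwl
targets: trim_reads
outputs_map:
  trimmed: FileName
inputs:
  infile: _FileName_
```

```{r step="qc_report_trim" kind="code" deps="fastq_stats_trim"}
files <- sort(Sys.glob("results/*.trimstats.txt"))
qc <- do.call(rbind, lapply(files, function(f) {
  x <- read.delim(f, stringsAsFactors = FALSE)
  data.frame(sample = sub("\\.trimstats\\.txt$", "", basename(f)),
             reads = x$value[x$metric == "lines"],
             bases = x$value[x$metric == "chars"])
}))
write.table(qc, "results/qc_trim.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

## Alignment

The reference is indexed once; trimmed reads are aligned per sample
against it, sorted, and summarised.

```{yaml step="index_reference" kind="cmd" deps="check_input"}
tool: param/mock_index.cwl
targets: targets_cohort.tsv
```

```{yaml step="align_reads" kind="cmd" deps="trim_reads,index_reference"}
tool: param/mock_align.cwl
targets: trim_reads
outputs_map:
  trimmed: FileName
inputs:
  reads: _FileName_
```

```{yaml step="sort_alignments" kind="cmd" deps="align_reads"}
tool: param/mock_sort.cwl
targets: align_reads
outputs_map:
  sam: FileName
inputs:
  insam: _FileName_
```

```{yaml step="alignment_stats" kind="cmd" deps="sort_alignments"}
tool: param/mock_alnstats.cwl
targets: sort_alignments
outputs_map:
  sorted: FileName
inputs:
  insam: _FileName_
```

```{r step="alignment_summary" kind="code" deps="alignment_stats"}
files <- sort(Sys.glob("results/*.alnstats.txt"))
aln <- do.call(rbind, lapply(files, function(f) {
  x <- read.delim(f, stringsAsFactors = FALSE)
  data.frame(sample = sub("\\.alnstats\\.txt$", "", basename(f)),
             alignments = x$value[x$metric == "alignments"],
             positions = x$value[x$metric == "positions"])
}))
write.table(aln, "results/alignment_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{yaml step="mark_duplicates" kind="cmd" deps="sort_alignments"}
tool: param/mock_dedup.cwl
targets: sort_alignments
outputs_map:
  sorted: FileName
inputs:
  insam: _FileName_
```

## Variant calling

Per-sample gVCF-style calling (scatter), then cohort-level joint
genotyping: the gather step consumes the complete set of per-sample
gVCF files in one many-to-one dependency.

```{yaml step="call_variants_gvcf" kind="cmd" deps="mark_duplicates,index_reference"}
tool: param/mock_gvcf.cwl
targets: mark_duplicates
outputs_map:
  dedup: FileName
inputs:
  aln: _FileName_
```

```{yaml step="joint_genotyping" kind="cmd" deps="call_variants_gvcf"}
tool: param/mock_joint.cwl
targets: targets_cohort.tsv
inputs:
  gvcfs:
    from_step: call_variants_gvcf
    output: gvcf
```

```{yaml step="filter_variants" kind="cmd" deps="joint_genotyping"}
tool: param/mock_filter.cwl
targets: targets_cohort.tsv
```

```{r step="variant_stats" kind="code" deps="filter_variants"}
flt <- read.delim("results/cohort.filtered.vcf", stringsAsFactors = FALSE,
                  check.names = FALSE)
names(flt)[1] <- sub("^#", "", names(flt)[1])
vs <- data.frame(
  metric = c("variants", "samples_with_calls", "genes", "mean_qual"),
  value = c(nrow(flt), length(unique(flt$SAMPLE)),
            length(unique(flt$GENE)), round(mean(flt$QUAL), 2)))
write.table(vs, "results/variant_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

## Functional annotation

```{yaml step="annotate_variants" kind="cmd" deps="filter_variants"}
tool: param/mock_annotate.cwl
targets: targets_cohort.tsv
```

```{r step="annotation_summary" kind="code" deps="annotate_variants"}
ann <- read.delim("results/cohort.annotated.tsv", stringsAsFactors = FALSE)
tab <- as.data.frame(table(ann$CONSEQUENCE), stringsAsFactors = FALSE)
names(tab) <- c("consequence", "count")
write.table(tab, "results/annotation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{r step="per_sample_variant_tables" kind="code" deps="annotate_variants"}
ann <- read.delim("results/cohort.annotated.tsv", stringsAsFactors = FALSE)
for (s in unique(ann$SAMPLE)) {
  sub <- ann[ann$SAMPLE == s, , drop = FALSE]
  write.table(sub, file.path("results", paste0(s, ".variants.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote", length(unique(ann$SAMPLE)), "per-sample variant tables\n")
```

## Cohort-level patterns

```{r step="variant_frequencies" kind="code" deps="annotate_variants"}
ann <- read.delim("results/cohort.annotated.tsv", stringsAsFactors = FALSE)
freq <- aggregate(cbind(count = POS) ~ GENE, data = ann, FUN = length)
freq$frequency <- round(freq$count / sum(freq$count), 4)
freq <- freq[order(-freq$count, freq$GENE), ]
write.table(freq, "results/variant_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{r step="shared_variant_patterns" kind="code" deps="variant_frequencies"}
ann <- read.delim("results/cohort.annotated.tsv", stringsAsFactors = FALSE)
byg <- tapply(ann$SAMPLE, ann$GENE, function(s) length(unique(s)))
nsamp <- length(unique(ann$SAMPLE))
pat <- data.frame(GENE = names(byg),
                  samples_with_variant = as.integer(byg))
pat$pattern <- ifelse(pat$samples_with_variant == nsamp, "shared",
                      ifelse(pat$samples_with_variant == 1, "private",
                             "partial"))
pat <- pat[order(pat$GENE), ]
write.table(pat, "results/shared_variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

```{r step="variant_composition_plot" kind="code" deps="variant_frequencies"}
freq <- read.delim("results/variant_frequencies.tsv",
                   stringsAsFactors = FALSE)
freq <- head(freq[order(-freq$count, freq$GENE), ], 10)
h <- 30 * nrow(freq) + 40
bars <- vapply(seq_len(nrow(freq)), function(i) {
  bw <- 300 * freq$count[i] / max(freq$count)
  sprintf(paste0('<g><rect x="100" y="%d" width="%.0f" height="20" ',
                 'fill="#74a9cf"/><text x="5" y="%d" font-size="12">%s',
                 '</text><text x="%.0f" y="%d" font-size="12">%d</text></g>'),
          30 * i, bw, 30 * i + 15, freq$GENE[i], 108 + bw, 30 * i + 15,
          freq$count[i])
}, character(1))
svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'width="440" height="%d">'), h),
         '<text x="5" y="20" font-size="14">Variant counts per gene</text>',
         bars, "</svg>")
writeLines(svg, "results/variant_composition.svg")
```

## Gene-level burden

Variants are aggregated at the gene level to quantify functional variant
burden across the cohort.

```{r step="gene_burden" kind="code" deps="annotate_variants"}
ann <- read.delim("results/cohort.annotated.tsv", stringsAsFactors = FALSE)
bm <- as.data.frame.matrix(table(ann$GENE, ann$SAMPLE))
bm <- cbind(GENE = rownames(bm), bm)
write.table(bm, "results/gene_burden_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{r step="burden_table" kind="code" deps="gene_burden"}
bm <- read.delim("results/gene_burden_matrix.tsv", stringsAsFactors = FALSE)
tot <- data.frame(GENE = bm$GENE,
                  burden = rowSums(bm[, -1, drop = FALSE]))
tot <- tot[order(-tot$burden, tot$GENE), ]
write.table(tot, "results/gene_burden.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

```{r step="burden_plot" kind="code" deps="burden_table"}
tot <- read.delim("results/gene_burden.tsv", stringsAsFactors = FALSE)
tot <- head(tot, 10)
h <- 30 * nrow(tot) + 40
bars <- vapply(seq_len(nrow(tot)), function(i) {
  bw <- 300 * tot$burden[i] / max(tot$burden)
  sprintf(paste0('<g><rect x="100" y="%d" width="%.0f" height="20" ',
                 'fill="#a1d99b"/><text x="5" y="%d" font-size="12">%s',
                 '</text><text x="%.0f" y="%d" font-size="12">%d</text></g>'),
          30 * i, bw, 30 * i + 15, tot$GENE[i], 108 + bw, 30 * i + 15,
          tot$burden[i])
}, character(1))
svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'width="440" height="%d">'), h),
         '<text x="5" y="20" font-size="14">Gene-level variant burden</text>',
         bars, "</svg>")
writeLines(svg, "results/gene_burden.svg")
```

## Pathway enrichment

A toy hypergeometric enrichment of high-burden genes over a bundled
20-gene / 3-pathway table.

```{r step="pathway_enrichment" kind="code" deps="gene_burden"}
pw <- read.delim("data/pathways.tsv", stringsAsFactors = FALSE)
tot <- read.delim("results/gene_burden.tsv", stringsAsFactors = FALSE)
universe <- pw$Gene
hits <- intersect(tot$GENE[tot$burden >= 2], universe)
paths <- split(pw$Gene, pw$Pathway)
enr <- data.frame(
  pathway = names(paths),
  size = vapply(paths, length, integer(1)),
  hits = vapply(paths, function(g) length(intersect(hits, g)), integer(1)))
enr$p_value <- signif(phyper(enr$hits - 1, enr$size,
                             length(universe) - enr$size, length(hits),
                             lower.tail = FALSE), 4)
write.table(enr, "results/pathway_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{r step="enrichment_table" kind="code" deps="pathway_enrichment"}
enr <- read.delim("results/pathway_enrichment.tsv", stringsAsFactors = FALSE)
enr$p_adjust <- signif(p.adjust(enr$p_value, "BH"), 4)
enr <- enr[order(enr$p_value, enr$pathway), ]
write.table(enr, "results/pathway_enrichment_ranked.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

## Drug-target mapping

Prioritized genes (high burden, enriched pathways) are mapped to known
drug targets to generate testable hypotheses.

```{r step="prioritize_genes" kind="code" deps="burden_table,enrichment_table"}
enr <- read.delim("results/pathway_enrichment_ranked.tsv",
                  stringsAsFactors = FALSE)
tot <- read.delim("results/gene_burden.tsv", stringsAsFactors = FALSE)
pw <- read.delim("data/pathways.tsv", stringsAsFactors = FALSE)
top_pw <- enr$pathway[enr$p_adjust <= 0.5]
if (!length(top_pw)) top_pw <- enr$pathway[1]
cand <- pw$Gene[pw$Pathway %in% top_pw]
pri <- tot[tot$GENE %in% cand & tot$burden >= 2, , drop = FALSE]
if (!nrow(pri)) pri <- head(tot, 3)
write.table(pri, "results/prioritized_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

```{r step="drug_target_map" kind="code" deps="prioritize_genes"}
dt <- read.delim("data/drug_targets.tsv", stringsAsFactors = FALSE)
pri <- read.delim("results/prioritized_genes.tsv", stringsAsFactors = FALSE)
dm <- merge(pri, dt, by.x = "GENE", by.y = "Gene")
dm <- dm[order(dm$GENE, dm$Drug), , drop = FALSE]
write.table(dm, "results/drug_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

```{r step="drug_table" kind="code" deps="drug_target_map"}
dm <- read.delim("results/drug_map.tsv", stringsAsFactors = FALSE)
if (nrow(dm)) {
  drugs <- aggregate(cbind(n_targets = GENE) ~ Drug, data = dm,
                     FUN = length)
  drugs$targets <- vapply(split(dm$GENE, dm$Drug),
                          paste, character(1), collapse = ",")
  drugs <- drugs[order(-drugs$n_targets, drugs$Drug), ]
} else {
  drugs <- data.frame(Drug = character(), n_targets = integer(),
                      targets = character())
}
write.table(drugs, "results/drug_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
```

## Reporting aids

```{r step="cohort_summary" kind="code" deps="variant_stats,annotation_summary,shared_variant_patterns"}
vs <- read.delim("results/variant_stats.tsv", stringsAsFactors = FALSE)
tab <- read.delim("results/annotation_summary.tsv", stringsAsFactors = FALSE)
pat <- read.delim("results/shared_variants.tsv", stringsAsFactors = FALSE)
txt <- c("Cohort summary",
         paste0("  ", vs$metric, ": ", vs$value),
         "Consequences:",
         paste0("  ", tab$consequence, ": ", tab$count),
         paste0("Shared genes: ", sum(pat$pattern == "shared"),
                "; private genes: ", sum(pat$pattern == "private")))
writeLines(txt, "results/cohort_summary.txt")
```

```{r step="session_info" kind="code" deps="load_config"}
writeLines(c(R.version.string,
             paste("platform:", R.version$platform)),
           "results/session_info.txt")
```

```{r step="export_results" kind="code" deps="drug_table,cohort_summary,variant_composition_plot,per_sample_variant_tables,burden_plot"}
files <- sort(setdiff(list.files("results", recursive = TRUE),
                      "manifest.tsv"))
info <- file.info(file.path("results", files))
man <- data.frame(file = files, bytes = info$size)
write.table(man, "results/manifest.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
```

```{r step="final_check" kind="code" deps="export_results,session_info,qc_report_raw,qc_report_trim,alignment_summary"}
need <- c("results/cohort.vcf", "results/cohort.filtered.vcf",
          "results/cohort.annotated.tsv", "results/gene_burden.tsv",
          "results/pathway_enrichment_ranked.tsv",
          "results/drug_candidates.tsv", "results/manifest.tsv")
stopifnot(file.exists(need))
writeLines("OK", "results/final_check.txt")
cat("workflow complete\n")
```
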