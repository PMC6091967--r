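# Shared fixtures, built in code at test time.

random_bases <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Mutate exactly k positions of a sequence (each to a different base).
mutate_k <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# A tiny hand-built reference database: 6 species, 2 orders, gapless
# 60-column alignment derived from two diverged ancestors.
toy_refdb <- function(seed = 99, seq_len = 60) {
  set.seed(seed)
  anc1 <- random_bases(1, seq_len)
  anc2 <- mutate_k(anc1, round(seq_len * 0.4))
  aln <- c(
    "Baetis lutheri"      = mutate_k(anc1, 2),
    "Baetis fuscatus"     = mutate_k(anc1, 3),
    "Ecdyonurus venosus"  = mutate_k(anc1, 8),
    "Dixella autumnalis"  = mutate_k(anc2, 2),
    "Macropelopia notata" = mutate_k(anc2, 3),
    "Simulium ornatum"    = mutate_k(anc2, 8))
  tax <- data.frame(
    species = names(aln),
    genus = sub(" .*", "", names(aln)),
    family = c("Baetidae", "Baetidae", "Heptageniidae", "Dixidae",
               "Chironomidae", "Simuliidae"),
    order = c("Ephemeroptera", "Ephemeroptera", "Ephemeroptera",
              "Diptera", "Diptera", "Diptera"),
    phylum = "Arthropoda", stringsAsFactors = FALSE)
  tree <- read_newick(paste0(
    "(((Baetis_lutheri:0.02,Baetis_fuscatus:0.03):0.05,",
    "Ecdyonurus_venosus:0.08):0.2,",
    "((Dixella_autumnalis:0.02,Macropelopia_notata:0.03):0.05,",
    "Simulium_ornatum:0.08):0.2);"))
  tree$tip.label <- gsub("_", " ", tree$tip.label, fixed = TRUE)
  ref_db(aln, tree, tax)
}

# Write records to a temp FASTA/FASTQ and return the path.
tmp_fasta <- function(records) {
  f <- tempfile(fileext = ".fasta")
  write_fasta(records, f)
  f
}

make_reads <- function(bases, sample_id = "S1", prefix = "r") {
  sequence_records(sprintf("%s%04d", prefix, seq_along(bases)), bases,
                   sample_id)
}

# Default primer from the pipeline configuration.
PRIMER <- pipeline_config()$primer_fwd
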