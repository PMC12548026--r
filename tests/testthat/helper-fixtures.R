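# Shared fixture builders. All fixtures are built in code; nothing binary.

# Minimal GSM with given characteristics lines (single channel).
gsm_with <- function(acc, chars = character(), ...) {
  gsm_record(accession = acc, channel_count = 1L,
             characteristics = list(chars), ...)
}

# A small hand-written SOFT corpus exercising entities, channel suffixes,
# repeated attributes, tables and values containing '='.
soft_fixture_text <- function() {
  paste(
    "^PLATFORM = GPL99",
    "!Platform_technology = in situ oligonucleotide",
    "!Platform_manufacturer = Affymetrix, Inc.",
    "!Platform_distribution = commercial",
    "#ID_REF = probe identifier",
    "#VALUE = normalized signal",
    "!Platform_table_begin",
    "ID_REF\tVALUE",
    "AFFX-1\t5.2",
    "!Platform_table_end",
    "^SAMPLE = GSM1",
    "!Sample_channel_count = 2",
    "!Sample_submission_date = Mar 05 2004",
    "!Sample_organism_ch1 = Escherichia coli",
    "!Sample_organism_ch2 = Escherichia coli",
    "!Sample_characteristics_ch1 = strain: MG1655",
    "!Sample_characteristics_ch1 = medium: LB",
    "!Sample_characteristics_ch2 = genotype: delta-lacZ x = y",
    "!Sample_platform_id = GPL99",
    "!Sample_label = Cy3",
    "!Sample_supplementary_file_1 = raw1.CEL.gz",
    "!Sample_supplementary_file_2 = scan.jpg",
    "^SAMPLE = GSM2",
    "!Sample_channel_count = 1",
    "!Sample_submission_date = Jan 20 2011",
    "!Sample_organism_ch1 = Bacillus subtilis",
    "!Sample_characteristics_ch1 = grown overnight in LB broth",
    "!Sample_library_strategy = RNA-Seq",
    "!Sample_platform_id = GPL100",
    sep = "\n")
}

# Small corpus configuration for fast property tests.
small_config <- function(n = 200L, seed = 42L, ...) {
  corpus_config(n_gsm = n, seed = seed, ...)
}

paper_logistic <- function() {
  logistic_fit(L = 45293.79, k = 0.3968, x0 = 2011.245)
}
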