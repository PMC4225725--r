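# Shared fixture constructors (built in code at test time).

# The MADS-box superfamily pair: type1 has the MADS box only, the
# MICK family adds the keratin-like K-box, which the type1 rule vetoes.
mads_rules <- function() {
  rule_table(
    family = c("MADS type1", "MADS-MICK"),
    category = "TF",
    must_have = c("IPR002100", "IPR002100&IPR002487"),
    prohibited = c("IPR002487", NA)
  )
}

# Four-rule table over the shared B3 / AP2 DNA-binding domains: B3 and
# AP2-EREBP veto each other's featured domain, RAV requires both, ARF
# requires B3 plus one of its two specific domains.
b3_ap2_rules <- function() {
  rule_table(
    family = c("B3", "AP2-EREBP", "RAV", "ARF"),
    category = "TF",
    must_have = c("IPR003340", "IPR001471", "IPR003340&IPR001471",
                  "(IPR010525|IPR011525)&IPR003340"),
    prohibited = c("IPR001471", "IPR003340", NA, NA)
  )
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# One InterProScan 5 TSV row with optional InterPro columns.
ips_row <- function(id, sig, start = 10, stop = 110, score = "1e-20",
                    ipr = "-", ipr_desc = "-") {
  paste(id, "d41d8cd98f00b204e9800998ecf8427e", "300", "Pfam", sig,
        "some domain", start, stop, score, "T", "01-01-2020", ipr, ipr_desc,
        sep = "\t")
}
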