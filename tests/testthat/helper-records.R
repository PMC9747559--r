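# Build schema-complete comparison records from the fields a test cares
# about; remaining columns get neutral defaults.
make_record <- function(consensus_binary, manual_class, automated_class,
                        case_count = 1L, manual_criteria = "",
                        automated_criteria = "", flags = "",
                        variant_key = "v1",
                        manual_date = as.Date("2020-06-01")) {
  data.frame(
    variant_key = variant_key,
    consensus_binary = consensus_binary,
    manual_class = manual_class,
    automated_class = automated_class,
    case_count = as.integer(case_count),
    manual_criteria = manual_criteria,
    automated_criteria = automated_criteria,
    flags = flags,
    manual_date = as.Date(manual_date),
    stringsAsFactors = FALSE
  )
}
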