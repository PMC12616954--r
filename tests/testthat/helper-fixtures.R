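# In-code fixtures shared across tests.

mk_config <- function(seg_txt, jn_txt, lengths) {
  seg <- parse_segments(seg_txt)
  jn <- parse_junctions(jn_txt, seg)
  dup_config(seg, jn, lengths)
}

# Two interspersed direct duplications on one chromosome (the archetype).
generic_config <- function() {
  mk_config(
    paste(
      "id\tchrom\tstart\tend\tgain",
      "D1\tchrA\t600001\t800000\t1",
      "D2\tchrA\t1100001\t1250000\t1",
      sep = "\n"
    ),
    "id\tjunction\thomology_bp\nJ1\t+D1:+D2\t0\nJ2\t+D2:+D1\t0",
    c(chrA = 2000000)
  )
}

tandem_config <- function() {
  mk_config(
    "id\tchrom\tstart\tend\tgain\nD\tchrA\t900001\t1100000\t1",
    "id\tjunction\thomology_bp\nJ\t+D:+D\t0",
    c(chrA = 2000000)
  )
}

# Reduced chromoanasynthesis-like configuration (four duplications plus a
# triplication, same junction pattern as the bundled case 3 but on small
# maps); small enough for the brute-force oracle.
case3_like_config <- function() {
  tabs <- ogmtopo:::fixture_tables("case3_like")
  seg <- parse_segments(tabs$segments)
  dup_config(seg, parse_junctions(tabs$junctions, seg), tabs$lengths)
}

keys_of <- function(set) unname(vapply(set, `[[`, "", "key"))

cycle_from_start <- function(chain, seg) ogmtopo:::cycle_from(chain, seg)

expect_same_structure_sets <- function(a, b) {
  expect_setequal(keys_of(a), keys_of(b))
}
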