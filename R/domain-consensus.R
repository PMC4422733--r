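# Synthetic domain consensus sequences used by the synthetic-data
# generator and (via the shipped seed alignments) by the domain profiles.
#
# These are constructed stand-ins for the four structural domains the
# pipeline vets (GST N-terminal, GST C-terminal, thioredoxin-like, MAPEG):
# fixed sequences with the right lengths and, for MAPEG, the conserved
# 16-residue motif VERVRRxHLNDxENIx embedded at columns 61-76.  They have
# no biological sequence content; their role is to give planted gene
# families a defined, detectable domain architecture.

DOMAIN_CONSENSUS <- list(
  GSTN = paste0("PQHAHNYWENNQHFMQHCWHWFGQYEPAGLGFFDTFDEYTATDYSNVKHM",
                "EQPRWELVTEQNTWITPATVIECCDQMQDN"),
  GSTC = paste0("IYRPSVGIEDSRHIVVLPKGTDRFTWVFGSQDDTHEVELQFNPDEWVDTG",
                "IPGLHIGPADVPQTSFGRGRAKFSCNEKGSCFCVDTKSNSCTTNMKYTKA"),
  THX  = paste0("HFFIIANEHPDWFPVERAIYPTDVSLRCSACDRRESSRGHGWYCNWLVKD",
                "YQYEVNFLGKPERDRCYYDSDYPNENWVEK"),
  MAPEG = paste0("SGPAKRQIKFDTNGTAPKMEAFWNCEWYRSTWFQSQPLPQCMMNFKVKKE",
                 "HYIVEQKQIYVERVRRAHLNDAENIAGEITLVGSYQYGKSTFHILRMWFV",
                 "DRHCFPMNYTMRVCDEISEQHQYEEFLMNDTHCEYWLHSRKMIM")
)

# The conserved MAPEG motif: fixed residues with x wildcards at the three
# variable positions; motif position 9 is the stereotypical leucine.
MAPEG_MOTIF_PATTERN <- "VERVRRxHLNDxENIx"
MAPEG_MOTIF_START <- 61L  # 1-based column of the motif within the domain

# Anchor columns: positions held invariant under all simulated divergence
# (catalytic/structural residues in a real family).  Every 6th column is
# anchored, which keeps the domains detectable by profile scoring while
# leaving cross-subclass identity near the background (subclasses share
# only these columns); for MAPEG the motif's fixed (non-wildcard) columns
# are anchored as well, so the motif survives arbitrary divergence.
domain_anchor_columns <- function(name) {
  width <- nchar(DOMAIN_CONSENSUS[[name]])
  anchors <- seq(1L, width, by = 6L)
  if (name == "MAPEG") {
    pat <- strsplit(MAPEG_MOTIF_PATTERN, "")[[1]]
    fixed <- which(pat != "x")
    anchors <- sort(union(anchors, MAPEG_MOTIF_START + fixed - 1L))
  }
  anchors
}
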