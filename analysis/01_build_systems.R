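#!/usr/bin/env Rscript
# Builds the two study systems -- the toy tRNA with and without the
# m2,2G modification at its G site -- and writes their native structures,
# domain definitions and native contact maps under results/.
#
# The toy carries the five tRNA domains (aas, asl, dsl, tsl, vl) with the
# modifiable guanosine sitting between the D-stem loop and the anticodon
# stem loop, base-paired to a variable-loop residue, mirroring the
# G27/A45 arrangement of the real molecule at pseudo-atom scale.

suppressPackageStartupMessages(library(gofold))
out <- "results/systems"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fixture <- make_mini_trna(stem_bp = 4, loop_len = 4)
s_unmod <- fixture$structure
s_mod <- apply_m22g(s_unmod, fixture$g_site)

write_frame(s_unmod, s_unmod$xyz, file.path(out, "native_unmodified.pdb"))
write_frame(s_mod, s_mod$xyz, file.path(out, "native_modified.pdb"))
write_domain_config(fixture$domains, file.path(out, "domains.cfg"))

for (tag in c("unmodified", "modified")) {
  s <- if (tag == "modified") s_mod else s_unmod
  cm <- build_native_contacts(s)
  write_contact_map(cm, file.path(out, paste0("contacts_", tag, ".tsv")))
  cat(sprintf("%s: %d residues, %d atoms, %d native contacts\n",
              tag, nrow(s$residues), nrow(s$atoms), nrow(cm$contacts)))
}
cat(sprintf("modifiable G site: residue %d (partner residue %d in vl)\n",
            fixture$g_site, fixture$g_partner))
cat(sprintf(
  "native G-site hydrogen bonds to partner: %d (unmodified) vs %d (modified)\n",
  hbond_count(s_unmod$xyz, s_unmod, fixture$g_site, fixture$g_partner),
  hbond_count(s_mod$xyz, s_mod, fixture$g_site, fixture$g_partner)
))
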