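MD summary tables consumed by the post-processing functions
(simulationSummary + enthalpyOfVaporization etc.).

The shipped file eth4si.tsv is a placeholder: the average potential
energies must be produced by running the exported topology in an external
MD engine under the documented protocol (see inst/templates/), then filled
in.  NA entries mark quantities not yet computed.

Columns: quantity, value, unit
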