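Place the original GenBank flat-file records for Octadecabacter arcticus
238 and Octadecabacter antarcticus 307 (chromosomes and plasmids, ~10 Mb
total, files ending .gb/.gbk/.gbff) in this directory and reinstall the
package to enable the deposited-record statistics check in the test
suite. The package performs no downloads and these records are too large
to bundle.
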