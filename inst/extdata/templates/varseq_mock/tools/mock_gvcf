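#!/bin/sh
# toy per-sample variant caller: emits a gVCF-like table with deterministic
# variants derived from alignment positions (gene assigned by position)
IN=""; IDX=""; SAMPLE=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -r) IDX="$2"; shift 2 ;;
    -s) SAMPLE="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$SAMPLE" ] && [ -n "$OUT" ] || { echo "usage: mock_gvcf -i aln -r idx -s sample -o out" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_gvcf: no such file: $IN" >&2; exit 1; }
[ -z "$IDX" ] || [ -f "$IDX" ] || { echo "mock_gvcf: missing index: $IDX" >&2; exit 1; }
{
  printf '#CHROM\tPOS\tGENE\tREF\tALT\tQUAL\tSAMPLE\n'
  awk -F'\t' -v OFS='\t' -v s="$SAMPLE" '{
    p = $3
    if (p % 3 == 0) {
      g = sprintf("GENE%02d", (p % 20) + 1)
      q = 30 + (p % 50)
      print "chr1", p, g, "A", "G", q, s
    }
  }' "$IN"
} > "$OUT"
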