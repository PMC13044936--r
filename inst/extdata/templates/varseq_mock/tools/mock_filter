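#!/bin/sh
# toy variant filter: keeps calls at or above a quality threshold
IN=""; OUT=""; MINQ=40
while [ $# -gt 0 ]; do
  case "$1" in
    -i) IN="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    --min-qual) MINQ="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$IN" ] && [ -n "$OUT" ] || { echo "usage: mock_filter -i in -o out [--min-qual q]" >&2; exit 2; }
[ -f "$IN" ] || { echo "mock_filter: no such file: $IN" >&2; exit 1; }
awk -F'\t' -v q="$MINQ" 'NR == 1 || $6 >= q' "$IN" > "$OUT"
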