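#!/bin/sh
# toy reference indexer: records a checksum of the reference
REF=""; OUT=""
while [ $# -gt 0 ]; do
  case "$1" in
    -r) REF="$2"; shift 2 ;;
    -o) OUT="$2"; shift 2 ;;
    *) shift ;;
  esac
done
[ -n "$REF" ] && [ -n "$OUT" ] || { echo "usage: mock_index -r ref -o out" >&2; exit 2; }
[ -f "$REF" ] || { echo "mock_index: no such file: $REF" >&2; exit 1; }
sum=$(cksum "$REF" | awk '{print $1}')
printf 'index\t%s\n' "$sum" > "$OUT"
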