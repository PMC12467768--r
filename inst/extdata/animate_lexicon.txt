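# Animate head nouns: animals, people and other body-capable agents.
# One word per line, lowercase singular; lines starting with '#' are ignored.
animal
ant
baby
bear
bee
bird
boxer
boy
butterfly
camel
cat
chicken
child
cow
crab
crane
dancer
deer
dog
dolphin
dragon
duck
eagle
elephant
fish
fox
frog
giraffe
girl
goat
goose
gymnast
horse
human
kangaroo
lady
lion
man
monkey
mouse
owl
penguin
person
pig
rabbit
runner
seal
shark
sheep
snake
spider
squirrel
swan
swimmer
tiger
turkey
turtle
whale
wolf
woman
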